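## Taxon-level attribution of imputed functions: who contributes what to
## each top-level functional category, averaged over samples.

#' Decompose imputed functions into per-taxon contributions
#'
#' For every (taxon at `rank`, level-1 category, sample) triple, sums the
#' imputed mass `norm[s, o] * gc[o, k]` over the OTUs of the taxon and the
#' gene families of the category. OTUs unresolved at the rank pool under
#' `"unclassified"`; gene families absent from the hierarchy count under
#' the `"Unclassified"` category.
#'
#' @param norm samples x OTUs copy-number-normalized abundances.
#' @param gc OTUs x functions gene-content matrix.
#' @param taxonomy data.frame with `otu_id` and rank columns.
#' @param hierarchy 4-column function hierarchy data.frame.
#' @param rank `"phylum"` or `"class"`.
#' @return 3-d array taxa x categories x samples.
#' @export
compute_contributions <- function(norm, gc, taxonomy, hierarchy,
                                  rank = c("phylum", "class")) {
  rank <- match.arg(rank)
  otus <- colnames(norm)
  gc <- gc[otus, , drop = FALSE]
  label <- stats::setNames(taxonomy[[rank]], taxonomy$otu_id)[otus]
  label[is.na(label)] <- "unclassified"
  cat_of <- stats::setNames(hierarchy$level1, hierarchy$function_id)
  fun_cat <- cat_of[colnames(gc)]
  fun_cat[is.na(fun_cat)] <- "Unclassified"
  # a multi-mapped gene family can sit in two L1 categories; use the first
  # mapping per function (deduplicated above through the named lookup)
  taxa <- sort(unique(label))
  cats <- sort(unique(fun_cat))
  out <- array(0, dim = c(length(taxa), length(cats), nrow(norm)),
               dimnames = list(taxa, cats, rownames(norm)))
  for (ct in cats) {
    gcc <- rowSums(gc[, fun_cat == ct, drop = FALSE])  # per-OTU copies in ct
    mass <- sweep(norm, 2, gcc, "*")                   # samples x OTUs
    for (tx in taxa) {
      out[tx, ct, ] <- rowSums(mass[, label == tx, drop = FALSE])
    }
  }
  out
}

#' Summarize a contribution tensor into attribution percentages
#'
#' Per sample, each taxon's mass in a category is expressed (i) as a
#' percentage of that category's total ("attribution of function", AAF)
#' and (ii) as a percentage of the grand total over all categories
#' ("attribution of total", AAT); percentages are then averaged
#' unweighted over samples. `TotalAA`, the row sum of AAT over
#' categories, therefore sums to 100 over taxa, as does each AAF column.
#'
#' @param tensor taxa x categories x samples array from
#'   [compute_contributions()].
#' @return list of class `attribution_summary` with matrices `AAF`, `AAT`
#'   (taxa x categories) and vector `TotalAA`.
#' @export
summarize_attribution <- function(tensor) {
  stopifnot(length(dim(tensor)) == 3)
  grand <- apply(tensor, 3, sum)
  keep <- grand > 0
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) with zero total mass excluded")
    tensor <- tensor[, , keep, drop = FALSE]
    grand <- grand[keep]
  }
  if (!dim(tensor)[3]) stop("no samples with positive mass")
  n_t <- dim(tensor)[1]; n_c <- dim(tensor)[2]; n_s <- dim(tensor)[3]
  cat_tot <- matrix(apply(tensor, c(2, 3), sum), n_c, n_s)
  AAF <- matrix(0, n_t, n_c, dimnames = dimnames(tensor)[1:2])
  AAT <- matrix(0, n_t, n_c, dimnames = dimnames(tensor)[1:2])
  for (ci in seq_len(n_c)) {
    sl <- matrix(tensor[, ci, , drop = FALSE], n_t, n_s)  # taxa x samples
    ok <- cat_tot[ci, ] > 0
    AAF[, ci] <- 100 * rowMeans(sweep(sl[, ok, drop = FALSE], 2,
                                      cat_tot[ci, ok], "/"))
    AAT[, ci] <- 100 * rowMeans(sweep(sl, 2, grand, "/"))
  }
  structure(list(AAF = AAF, AAT = AAT, TotalAA = rowSums(AAT),
                 n_samples = n_s),
            class = "attribution_summary")
}

#' Rank taxa by their attribution within a category
#'
#' @param summary an `attribution_summary`.
#' @param category a level-1 category name.
#' @return data.frame of taxa sorted by descending AAF (ties broken
#'   lexicographically), with AAF, AAT and TotalAA columns.
#' @export
dominant_taxa <- function(summary, category) {
  stopifnot(inherits(summary, "attribution_summary"))
  if (!category %in% colnames(summary$AAF)) {
    stop("unknown category: ", category)
  }
  aaf <- stats::setNames(summary$AAF[, category], rownames(summary$AAF))
  ord <- order(-aaf, names(aaf))
  data.frame(taxon = names(aaf)[ord], AAF = unname(aaf[ord]),
             AAT = unname(summary$AAT[ord, category]),
             TotalAA = unname(summary$TotalAA[ord]),
             stringsAsFactors = FALSE)
}

#' @export
print.attribution_summary <- function(x, ...) {
  cat("Attribution summary over", x$n_samples, "samples;",
      nrow(x$AAF), "taxa x", ncol(x$AAF), "categories\n")
  top <- sort(x$TotalAA, decreasing = TRUE)
  cat("Top contributors (TotalAA):",
      paste(sprintf("%s=%.2f", names(top)[seq_len(min(3, length(top)))],
                    top[seq_len(min(3, length(top)))]), collapse = ", "),
      "\n")
  invisible(x)
}
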