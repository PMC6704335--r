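## Marker-gene metagenome imputation: 16S copy-number normalization,
## gene-content multiplication, pathway collapse, shared-function sets.

#' Normalize an OTU table by 16S rRNA copy number
#'
#' Divides every count by the operon copy number of its OTU, converting
#' read abundance into an approximation of cell abundance. OTUs missing
#' from `copies` fall back to `default_copy` with a warning (the usual
#' convention for unannotated reference tips).
#'
#' @param table samples x OTUs matrix.
#' @param copies named vector of copy numbers (> 0).
#' @param default_copy fallback copy number for unannotated OTUs.
#' @return samples x OTUs matrix of normalized abundances.
#' @export
normalize_copy_number <- function(table, copies, default_copy = 1) {
  otus <- colnames(table)
  missing <- setdiff(otus, names(copies))
  if (length(missing)) {
    warning(length(missing), " OTU(s) without 16S copy number; using ",
            default_copy)
  }
  cn <- stats::setNames(rep(default_copy, length(otus)), otus)
  known <- intersect(otus, names(copies))
  cn[known] <- copies[known]
  if (any(cn <= 0)) {
    stop("non-positive 16S copy number for: ",
         paste(otus[cn <= 0], collapse = ", "))
  }
  sweep(table, 2, cn, "/")
}

#' Predict the metagenome from normalized abundances
#'
#' The imputed profile is the linear combination of reference gene content
#' weighted by normalized taxon abundance:
#' `F[s, k] = sum_o norm[s, o] * gc[o, k]`.
#'
#' @param norm samples x OTUs normalized abundance matrix.
#' @param gc OTUs x functions gene-content matrix; must cover every OTU in
#'   `norm`.
#' @return samples x functions matrix with attribute `level = "gene"`.
#' @export
predict_metagenome <- function(norm, gc) {
  missing <- setdiff(colnames(norm), rownames(gc))
  if (length(missing)) {
    stop("OTU(s) absent from the gene-content matrix: ",
         paste(missing, collapse = ", "))
  }
  out <- norm %*% gc[colnames(norm), , drop = FALSE]
  attr(out, "level") <- "gene"
  out
}

#' Collapse a gene-level profile to a pathway level
#'
#' A gene family mapping to m pathways contributes its full value to each
#' of the m (no splitting), matching the standard categorize-by-function
#' collapse. Functions absent from the hierarchy are dropped with a
#' warning stating how many.
#'
#' @param profile samples x gene-family matrix.
#' @param hierarchy 4-column data.frame (`function_id`, `level3`, `level2`,
#'   `level1`).
#' @param level `"L3"`, `"L2"` or `"L1"`.
#' @return samples x pathways matrix with attribute `level`.
#' @export
collapse_to_level <- function(profile, hierarchy, level = c("L3", "L2", "L1")) {
  level <- match.arg(level)
  col <- c(L3 = "level3", L2 = "level2", L1 = "level1")[[level]]
  mp <- unique(hierarchy[, c("function_id", col)])
  known <- colnames(profile) %in% mp$function_id
  n_drop <- sum(!known)
  if (n_drop) {
    warning(n_drop, " function(s) missing from the hierarchy were dropped")
  }
  mp <- mp[mp$function_id %in% colnames(profile), , drop = FALSE]
  targets <- sort(unique(mp[[col]]))
  out <- matrix(0, nrow(profile), length(targets),
                dimnames = list(rownames(profile), targets))
  for (t in targets) {
    cols <- mp$function_id[mp[[col]] == t]
    out[, t] <- rowSums(profile[, cols, drop = FALSE])
  }
  attr(out, "level") <- level
  out
}

#' Set analysis of functions detected per group
#'
#' A function is "present" in a group when the presence rule holds on that
#' group's sub-profile (default: a nonzero value in at least
#' `min_samples` samples). Returns the size of every exclusive region of
#' the Venn diagram plus each group's presence set.
#'
#' @param profiles named list (one entry per group) of samples x functions
#'   matrices over the same function universe.
#' @param min_samples minimum number of samples with a nonzero value for a
#'   function to count as present.
#' @param presence_rule optional function(matrix) -> logical vector over
#'   functions, overriding the default rule.
#' @return list with `sets` (named list of character vectors), `regions`
#'   (named integer vector over exclusive membership patterns such as
#'   `"A&B"`), and `common` (count present in every group).
#' @export
venn_functions <- function(profiles, min_samples = 1, presence_rule = NULL) {
  if (length(profiles) < 2) stop("need at least two groups")
  if (is.null(presence_rule)) {
    presence_rule <- function(m) colSums(m > 0) >= min_samples
  }
  sets <- lapply(profiles, function(m) colnames(m)[presence_rule(m)])
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (is.null(dim(membership))) membership <- matrix(membership, nrow = 1)
  pattern <- apply(membership, 1, function(row)
    paste(names(sets)[row], collapse = "&"))
  regions <- table(pattern)
  all_key <- paste(names(sets), collapse = "&")
  list(sets = sets,
       regions = stats::setNames(as.integer(regions), names(regions)),
       common = sum(pattern == all_key))
}
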