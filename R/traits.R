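## Organism-level phenotype traits: abundance-weighted trait shares per
## sample, phylum breakdowns, and stratum summaries.

#' Aggregate organism traits into per-sample relative shares
#'
#' The share of a trait in a sample is the abundance-weighted mean of the
#' trait membership over OTUs:
#' `profile[s, t] = sum_o norm[s, o] * traits[o, t] / sum_o norm[s, o]`.
#' Because the weights are ratios, the result is invariant to rescaling a
#' sample's counts. Samples with zero total abundance are excluded with a
#' warning; OTUs absent from the trait table count as membership 0.
#'
#' @param norm samples x OTUs normalized abundances.
#' @param traits OTUs x traits membership matrix, values in `[0,1]`.
#' @return samples x traits matrix of shares in `[0,1]`.
#' @export
aggregate_traits <- function(norm, traits) {
  if (!length(intersect(colnames(norm), rownames(traits)))) {
    stop("the trait table covers none of the OTUs")
  }
  tr <- matrix(0, ncol(norm), ncol(traits),
               dimnames = list(colnames(norm), colnames(traits)))
  common <- intersect(colnames(norm), rownames(traits))
  tr[common, ] <- traits[common, , drop = FALSE]
  tot <- rowSums(norm)
  keep <- tot > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-abundance sample(s) excluded")
  }
  out <- (norm[keep, , drop = FALSE] %*% tr) / tot[keep]
  out
}

#' Phylum breakdown of each trait's abundance mass
#'
#' Partitions the trait-bearing mass of every (trait, sample) pair by
#' phylum; shares sum to 1 where the trait-bearing mass is positive and
#' are `NA` where it is zero.
#'
#' @inheritParams aggregate_traits
#' @param taxonomy data.frame with `otu_id` and `phylum` columns.
#' @return 3-d array traits x phyla x samples of shares.
#' @export
trait_phylum_breakdown <- function(norm, traits, taxonomy) {
  common <- intersect(colnames(norm), rownames(traits))
  norm <- norm[, common, drop = FALSE]
  tr <- traits[common, , drop = FALSE]
  phylum <- stats::setNames(taxonomy$phylum, taxonomy$otu_id)[common]
  phylum[is.na(phylum)] <- "unclassified"
  phyla <- sort(unique(phylum))
  out <- array(NA_real_,
               dim = c(ncol(tr), length(phyla), nrow(norm)),
               dimnames = list(colnames(tr), phyla, rownames(norm)))
  for (t in colnames(tr)) {
    mass <- sweep(norm, 2, tr[, t], "*")     # samples x OTUs
    by_ph <- vapply(phyla, function(ph)
      rowSums(mass[, phylum == ph, drop = FALSE]),
      numeric(nrow(norm)))
    if (is.null(dim(by_ph))) by_ph <- matrix(by_ph, nrow = nrow(norm))
    tot <- rowSums(by_ph)
    pos <- tot > 0
    shares <- by_ph
    shares[pos, ] <- by_ph[pos, , drop = FALSE] / tot[pos]
    shares[!pos, ] <- NA_real_
    out[t, , ] <- t(shares)
  }
  out
}

#' Per-stratum means and dispersions of trait shares
#'
#' @param profile samples x traits matrix from [aggregate_traits()].
#' @param metadata data.frame with `sample_id`, `group`, `gender`.
#' @return data.frame with one row per (gender, group, trait): `mean`,
#'   `sd`, `n`.
#' @export
group_trait_summary <- function(profile, metadata) {
  meta <- metadata[match(rownames(profile), metadata$sample_id), ]
  if (anyNA(meta$sample_id)) stop("metadata missing for some samples")
  out <- list()
  for (g in unique(meta$gender)) {
    for (grp in unique(meta$group[meta$gender == g])) {
      idx <- meta$gender == g & meta$group == grp
      sub <- profile[idx, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        gender = g, group = grp, trait = colnames(sub),
        mean = colMeans(sub),
        sd = apply(sub, 2, stats::sd),
        n = sum(idx), row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
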