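## Published summary tables for the cohort the synthetic generator
## emulates (the original study deposits no raw data, so these printed
## summaries are the only external anchors). Used for internal-consistency
## checks: the density identity, the attribution accounting, and the
## level-3 signature inventory.

ref_path <- function(file) {
  p <- system.file("extdata", file, package = "imputome")
  if (!nzchar(p)) stop("reference fixture not found: ", file)
  p
}

#' Reference network property table
#'
#' Node/edge counts (ordered-pair convention) and topology metrics
#' reported for the six (gender, group) functional networks of the
#' original cohort.
#' @return data.frame with one row per network.
#' @export
reference_network_metrics <- function() {
  utils::read.delim(ref_path("reference_network_metrics.tsv"),
                    stringsAsFactors = FALSE)
}

#' Reference phylum-level attribution table (female stratum)
#'
#' Per-phylum attribution percentages over the five level-1 functional
#' categories: attribution of function (AAF), attribution of total (AAT)
#' and the per-phylum total (TotalAA).
#' @return data.frame with one row per (phylum, category).
#' @export
reference_attribution_female <- function() {
  utils::read.delim(ref_path("reference_phylum_attribution_female.tsv"),
                    stringsAsFactors = FALSE)
}

#' Reference level-3 signature inventory (female stratum, one-against-all
#' mode)
#'
#' The 71 level-3 pathway signatures reported for the female cohort with
#' their enriched group.
#' @return data.frame with `group`, `id`, `function.`
#' @export
reference_level3_signatures <- function() {
  utils::read.delim(ref_path("reference_level3_signatures_female.tsv"),
                    stringsAsFactors = FALSE)
}
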