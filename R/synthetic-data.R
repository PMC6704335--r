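#' Synthetic cohort configuration
#'
#' Builds the configuration object consumed by [generate_cohort()]. The
#' defaults emulate the study design the package targets: a two-gender
#' cohort of 63 females (29 Vata, 11 Pitta, 23 Kapha) and 50 males
#' (13 Vata, 18 Pitta, 19 Kapha) with Firmicutes/Bacteroidetes-dominated
#' compositions, overdispersed 16S counts, and optional planted
#' group-enriched functional effects.
#'
#' @param group_sizes named list, one element per gender (`F`, `M`), each a
#'   named integer vector of per-group sample counts over
#'   `c(Vata, Pitta, Kapha)`.
#' @param n_otus number of background OTUs (marker OTUs for planted effects
#'   are appended on top of these).
#' @param phylum_mix named numeric vector of expected phylum-level relative
#'   abundances; must sum to 1.
#' @param n_functions number of gene families.
#' @param n_pathways_l3,n_pathways_l2 number of level-3 / level-2 pathway
#'   ids in the synthetic hierarchy (level 1 is the five fixed functional
#'   categories).
#' @param planted_effects list of effects created with [plant_effect()].
#' @param sequencing_depth reads per sample (row sum of the OTU table).
#' @param dispersion Dirichlet concentration governing between-sample
#'   overdispersion; smaller values give noisier compositions.
#' @param seed integer seed; one seed governs every draw in the generator.
#' @return a `cohort_config` list, validated.
#' @export
cohort_config <- function(group_sizes = list(
                            F = c(Vata = 29, Pitta = 11, Kapha = 23),
                            M = c(Vata = 13, Pitta = 18, Kapha = 19)),
                          n_otus = 150,
                          phylum_mix = c(Firmicutes = 0.55,
                                         Bacteroidetes = 0.33,
                                         Proteobacteria = 0.06,
                                         Actinobacteria = 0.03,
                                         Fusobacteria = 0.015,
                                         Tenericutes = 0.015),
                          n_functions = 200,
                          n_pathways_l3 = 30,
                          n_pathways_l2 = 10,
                          planted_effects = list(),
                          sequencing_depth = 10000,
                          dispersion = 300,
                          seed = 1L) {
  stopifnot(is.list(group_sizes), length(group_sizes) >= 1)
  for (g in names(group_sizes)) {
    sz <- group_sizes[[g]]
    if (any(sz < 2)) {
      stop("every (gender, group) stratum needs at least 2 samples; ",
           "gender ", g, " has ", paste(sz, collapse = "/"))
    }
  }
  if (n_otus <= 0 || n_functions <= 0 || n_pathways_l3 <= 0 ||
      n_pathways_l2 <= 0 || sequencing_depth <= 0 || dispersion <= 0) {
    stop("all counts and rates in the configuration must be positive")
  }
  if (abs(sum(phylum_mix) - 1) > 1e-9) {
    stop("phylum_mix must sum to 1 (got ", sum(phylum_mix), ")")
  }
  for (pe in planted_effects) {
    stopifnot(is.list(pe), !is.null(pe$group), !is.null(pe$fold))
    if (pe$fold <= 0) stop("planted fold-changes must be > 0")
  }
  structure(list(group_sizes = group_sizes, n_otus = as.integer(n_otus),
                 phylum_mix = phylum_mix,
                 n_functions = as.integer(n_functions),
                 n_pathways_l3 = as.integer(n_pathways_l3),
                 n_pathways_l2 = as.integer(n_pathways_l2),
                 planted_effects = planted_effects,
                 sequencing_depth = sequencing_depth,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Describe a planted group-enriched functional effect
#'
#' @param group group whose samples carry the enrichment (`"Vata"`,
#'   `"Pitta"` or `"Kapha"`).
#' @param functions character vector of function ids (e.g. `"F0007"`) to
#'   enrich.
#' @param fold multiplicative fold-change (> 0) applied to the abundance of
#'   the marker OTUs feeding those functions in the target stratum.
#' @param gender `"F"`, `"M"`, or `NA` for both genders.
#' @export
plant_effect <- function(group, functions, fold, gender = NA) {
  list(group = group, gender = gender,
       functions = as.character(functions), fold = fold)
}

# Fixed level-1 functional categories (the fifth mirrors the "Unclassified"
# category that reference gene catalogues carry).
L1_CATEGORIES <- c("Cellular Processes", "Environmental Information Processing",
                   "Genetic Information Processing", "Metabolism",
                   "Unclassified")

TRAIT_VOCABULARY <- c("aerobic", "anaerobic", "facultative_anaerobic",
                      "gram_negative", "gram_positive", "potential_pathogen",
                      "mobile_elements", "biofilm_formation",
                      "stress_tolerance")

# internal constants of the planted-effect mechanism (see methods vignette)
.MARKERS_PER_FUNCTION <- 2L
.MARKER_COPIES <- 30
.MARKER_REL_ABUNDANCE <- 0.001   # per marker OTU, of total community
.PLANTED_BG_ATTENUATION <- 0.1   # background gene-content damping

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Generate a complete synthetic cohort bundle
#'
#' Draws a seeded, fully reproducible input bundle: an OTU count table
#' (Dirichlet-multinomial per sample), greengenes-style taxonomy, 16S copy
#' numbers, a sparse taxon-by-function gene-content matrix with
#' phylum-specific rate profiles, a 3-level pathway hierarchy, a binary
#' organism-trait table, sample metadata, and an echo of the planted truth.
#'
#' Planted effects are realized through dedicated low-abundance marker OTUs
#' whose gene content concentrates on the planted functions; the marker
#' abundance is scaled by the fold-change in the target stratum, so the
#' enrichment propagates to the imputed functional profile while leaving
#' the rest of the community nearly untouched.
#'
#' @param config a [cohort_config()].
#' @return a `synthetic_bundle` list with elements `otu_table` (samples x
#'   OTUs integer matrix), `taxonomy` (data.frame), `copy_numbers` (named
#'   integer vector), `gene_content` (OTUs x functions matrix), `hierarchy`
#'   (4-column data.frame), `traits` (OTUs x traits 0/1 matrix), `metadata`
#'   (data.frame with `sample_id`, `group`, `gender`) and `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  # every block draws under its own seed derived from the one config seed,
  # so stages that do not depend on the planted effects (hierarchy, gene
  # content rates, taxonomy) are identical between a null and a planted
  # configuration sharing a seed
  block_seed <- function(k) set.seed(config$seed + k)
  block_seed(0L)

  ## ---- samples and metadata ----
  meta <- do.call(rbind, lapply(names(config$group_sizes), function(g) {
    sz <- config$group_sizes[[g]]
    do.call(rbind, lapply(names(sz), function(grp) {
      data.frame(group = rep(grp, sz[[grp]]), gender = g,
                 stringsAsFactors = FALSE)
    }))
  }))
  n_samples <- nrow(meta)
  meta$sample_id <- sprintf("S%03d", seq_len(n_samples))
  meta <- meta[, c("sample_id", "group", "gender")]

  ## ---- OTUs: phylum assignment and baseline means ----
  phyla <- names(config$phylum_mix)
  n_per <- pmax(1L, round(config$n_otus * config$phylum_mix))
  # adjust to hit n_otus exactly, favouring the largest phylum
  n_per[which.max(n_per)] <- n_per[which.max(n_per)] +
    (config$n_otus - sum(n_per))
  otu_phylum <- rep(phyla, times = n_per)
  base_mean <- stats::rlnorm(config$n_otus, meanlog = 0, sdlog = 1)
  # scale within each phylum so expected phylum totals match phylum_mix
  for (ph in phyla) {
    idx <- otu_phylum == ph
    base_mean[idx] <- base_mean[idx] / sum(base_mean[idx]) *
      config$phylum_mix[[ph]]
  }

  ## ---- marker OTUs for planted effects ----
  planted_functions <- unique(unlist(lapply(config$planted_effects,
                                            `[[`, "functions")))
  marker_map <- list()  # function id -> marker OTU indices
  if (length(planted_functions)) {
    for (f in planted_functions) {
      ids <- length(base_mean) + seq_len(.MARKERS_PER_FUNCTION)
      base_mean <- c(base_mean, rep(.MARKER_REL_ABUNDANCE,
                                    .MARKERS_PER_FUNCTION))
      otu_phylum <- c(otu_phylum, rep("Firmicutes", .MARKERS_PER_FUNCTION))
      marker_map[[f]] <- ids
    }
    base_mean <- base_mean / sum(base_mean)
  }
  n_otus_total <- length(base_mean)
  otu_ids <- sprintf("OTU_%04d", seq_len(n_otus_total))

  ## ---- per-sample fold multipliers from planted effects ----
  fold_matrix <- matrix(1, n_samples, n_otus_total)  # samples x OTUs
  truth <- list()
  for (pe in config$planted_effects) {
    target <- meta$group == pe$group &
      (is.na(pe$gender) | meta$gender == pe$gender)
    for (f in pe$functions) {
      fold_matrix[target, marker_map[[f]]] <-
        fold_matrix[target, marker_map[[f]]] * pe$fold
    }
    truth[[length(truth) + 1L]] <- data.frame(
      group = pe$group, gender = ifelse(is.na(pe$gender), "both", pe$gender),
      function_id = pe$functions, fold = pe$fold,
      marker_otus = vapply(pe$functions, function(f)
        paste(otu_ids[marker_map[[f]]], collapse = ","), ""),
      stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(group = character(), gender = character(),
               function_id = character(), fold = numeric(),
               marker_otus = character())

  ## ---- counts: Dirichlet-multinomial per sample ----
  block_seed(1L)
  counts <- matrix(0L, n_samples, n_otus_total,
                   dimnames = list(meta$sample_id, otu_ids))
  for (s in seq_len(n_samples)) {
    mu <- base_mean * fold_matrix[s, ]
    mu <- mu / sum(mu)
    p <- rdirichlet1(config$dispersion * mu)
    counts[s, ] <- as.integer(stats::rmultinom(1, config$sequencing_depth, p))
  }

  ## ---- 16S copy numbers ----
  block_seed(2L)
  copy_numbers <- stats::setNames(sample(1:7, n_otus_total, replace = TRUE),
                                  otu_ids)

  ## ---- taxonomy ----
  block_seed(3L)
  classes_of <- paste0(substr(otu_phylum, 1, 4), "ia_",
                       1 + (seq_len(n_otus_total) %% 2))
  taxonomy <- data.frame(
    otu_id = otu_ids,
    kingdom = "Bacteria",
    phylum = otu_phylum,
    class = classes_of,
    order = ifelse(stats::runif(n_otus_total) < 0.15, "unclassified",
                   paste0("Order_", substr(otu_phylum, 1, 3))),
    family = "unclassified",
    genus = sprintf("Genus_%03d", sample.int(60, n_otus_total, replace = TRUE)),
    species = "unclassified",
    stringsAsFactors = FALSE)

  ## ---- gene content: sparse Poisson with phylum rate profiles ----
  block_seed(4L)
  fun_ids <- sprintf("F%04d", seq_len(config$n_functions))
  profile <- matrix(stats::rlnorm(length(phyla) * config$n_functions,
                                  meanlog = 0, sdlog = 0.6),
                    length(phyla), config$n_functions,
                    dimnames = list(phyla, fun_ids))
  base_rate <- 0.4
  lambda <- base_rate * profile[otu_phylum, , drop = FALSE]
  if (length(planted_functions)) {
    lambda[, planted_functions] <- lambda[, planted_functions] *
      .PLANTED_BG_ATTENUATION
  }
  gene_content <- matrix(stats::rpois(length(lambda), lambda),
                         n_otus_total, config$n_functions,
                         dimnames = list(otu_ids, fun_ids))
  for (f in names(marker_map)) {
    gene_content[marker_map[[f]], ] <- stats::rpois(
      .MARKERS_PER_FUNCTION * config$n_functions, 0.05 * base_rate)
    gene_content[marker_map[[f]], f] <- .MARKER_COPIES
  }

  ## ---- function hierarchy ----
  block_seed(5L)
  l3_ids <- sprintf("L3_%02d", seq_len(config$n_pathways_l3))
  l2_ids <- sprintf("L2_%02d", seq_len(config$n_pathways_l2))
  l3_to_l2 <- stats::setNames(sample(l2_ids, config$n_pathways_l3,
                                     replace = TRUE), l3_ids)
  l2_to_l1 <- stats::setNames(sample(L1_CATEGORIES, config$n_pathways_l2,
                                     replace = TRUE), l2_ids)
  n_maps <- 1L + (stats::runif(config$n_functions) < 0.2)
  hier <- do.call(rbind, lapply(seq_len(config$n_functions), function(i) {
    l3 <- sample(l3_ids, n_maps[i])
    data.frame(function_id = fun_ids[i], level3 = l3,
               level2 = unname(l3_to_l2[l3]),
               level1 = unname(l2_to_l1[l3_to_l2[l3]]),
               stringsAsFactors = FALSE)
  }))

  ## ---- organism traits ----
  block_seed(6L)
  oxy_prob <- list(Firmicutes = c(0.05, 0.85, 0.10),
                   Bacteroidetes = c(0.02, 0.93, 0.05),
                   Proteobacteria = c(0.30, 0.30, 0.40),
                   Actinobacteria = c(0.25, 0.50, 0.25),
                   Fusobacteria = c(0.02, 0.93, 0.05),
                   Tenericutes = c(0.10, 0.70, 0.20))
  gram_pos_prob <- c(Firmicutes = 0.95, Bacteroidetes = 0.02,
                     Proteobacteria = 0.02, Actinobacteria = 0.95,
                     Fusobacteria = 0.02, Tenericutes = 0.5)
  other_prob <- c(potential_pathogen = 0.12, mobile_elements = 0.35,
                  biofilm_formation = 0.30, stress_tolerance = 0.25)
  traits <- matrix(0, n_otus_total, length(TRAIT_VOCABULARY),
                   dimnames = list(otu_ids, TRAIT_VOCABULARY))
  for (i in seq_len(n_otus_total)) {
    pr <- oxy_prob[[otu_phylum[i]]]
    if (is.null(pr)) pr <- c(1, 1, 1) / 3
    oxy <- sample(c("aerobic", "anaerobic", "facultative_anaerobic"), 1,
                  prob = pr)
    traits[i, oxy] <- 1
    gp <- gram_pos_prob[[otu_phylum[i]]]
    if (is.null(gp) || is.na(gp)) gp <- 0.5
    traits[i, if (stats::runif(1) < gp) "gram_positive" else "gram_negative"] <- 1
    for (tr in names(other_prob)) {
      traits[i, tr] <- as.numeric(stats::runif(1) < other_prob[[tr]])
    }
  }

  bundle <- list(otu_table = counts, taxonomy = taxonomy,
                 copy_numbers = copy_numbers, gene_content = gene_content,
                 hierarchy = hier, traits = traits, metadata = meta,
                 truth = truth, config = config)
  class(bundle) <- "synthetic_bundle"
  bundle
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("Synthetic cohort bundle:", nrow(x$otu_table), "samples x",
      ncol(x$otu_table), "OTUs;", ncol(x$gene_content), "gene families;",
      nrow(x$truth), "planted effect rows\n")
  invisible(x)
}
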