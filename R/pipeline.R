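## End-to-end orchestration: simulate or ingest, impute, collapse,
## attribute, aggregate traits, discover signatures per gender stratum,
## and build per-stratum networks, with a checksummed artifact manifest.

#' Pipeline run configuration
#'
#' Collects every stage parameter with the study's printed settings as
#' defaults: rank-test alpha 0.05, log-LDA threshold 2.0, q-value cutoff
#' 0.05, count filter 2 at 20% prevalence, 10% low-variance drop, 10000
#' network permutations, edge cutoff 0.01.
#'
#' @param cohort either a [cohort_config()] to simulate from, or a
#'   directory holding the input files written by [write_bundle()].
#' @param out_dir output directory.
#' @param levels pathway levels to analyze for signatures.
#' @param kw_alpha,lda_min,lefse_mode,q_max,min_count,min_prevalence,
#'   variance_drop,css_quantile,rf_top,network_B,edge_alpha stage
#'   parameters (see module functions).
#' @param network_level profile level used for the networks.
#' @param seed integer seed for every stochastic stage.
#' @return a `run_config` list.
#' @export
run_config <- function(cohort, out_dir, levels = c("L3", "L2"),
                       kw_alpha = 0.05, lda_min = 2.0,
                       lefse_mode = "less-strict", q_max = 0.05,
                       min_count = 2, min_prevalence = 0.20,
                       variance_drop = 0.10, css_quantile = 0.5,
                       rf_top = 30, network_B = 10000, edge_alpha = 0.01,
                       network_level = "L3", seed = 1L) {
  if (!inherits(cohort, "cohort_config")) {
    stopifnot(is.character(cohort))
    if (!dir.exists(cohort)) stop("input directory not found: ", cohort)
    for (f in c("otu_table.tsv", "metadata.tsv", "gene_content.tsv",
                "copy_numbers.tsv", "hierarchy.tsv", "taxonomy.tsv",
                "traits.tsv")) {
      if (!file.exists(file.path(cohort, f))) {
        stop("missing input file: ", file.path(cohort, f))
      }
    }
  }
  structure(list(cohort = cohort, out_dir = out_dir, levels = levels,
                 kw_alpha = kw_alpha, lda_min = lda_min,
                 lefse_mode = lefse_mode, q_max = q_max,
                 min_count = min_count, min_prevalence = min_prevalence,
                 variance_drop = variance_drop, css_quantile = css_quantile,
                 rf_top = rf_top, network_B = network_B,
                 edge_alpha = edge_alpha, network_level = network_level,
                 seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis
#'
#' Executes every stage and writes each artifact as TSV under
#' `cfg$out_dir`, returning (and writing) a manifest with per-artifact
#' MD5 checksums. Identical configurations and seeds yield identical
#' checksums. Genders are always analyzed as separate strata.
#'
#' @param cfg a [run_config()].
#' @return data.frame manifest (`artifact`, `path`, `md5`), invisibly
#'   written to `manifest.tsv`.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  add <- function(name, path) paths[[name]] <<- path

  if (inherits(cfg$cohort, "cohort_config")) {
    bundle <- stage("simulate", generate_cohort(cfg$cohort))
    in_dir <- file.path(cfg$out_dir, "inputs")
    bp <- stage("simulate", write_bundle(bundle, in_dir))
    for (nm in names(bp)) add(paste0("input_", nm), bp[[nm]])
  } else {
    bundle <- stage("ingest", list(
      otu_table = read_otu_table(file.path(cfg$cohort, "otu_table.tsv"),
                                 read_metadata(file.path(cfg$cohort,
                                                         "metadata.tsv"))),
      taxonomy = read_lineages(file.path(cfg$cohort, "taxonomy.tsv")),
      copy_numbers = read_copy_numbers(file.path(cfg$cohort,
                                                 "copy_numbers.tsv")),
      gene_content = read_gene_content(file.path(cfg$cohort,
                                                 "gene_content.tsv")),
      hierarchy = read_hierarchy(file.path(cfg$cohort, "hierarchy.tsv")),
      traits = read_traits(file.path(cfg$cohort, "traits.tsv")),
      metadata = read_metadata(file.path(cfg$cohort, "metadata.tsv"))))
  }
  meta <- bundle$metadata

  ## impute
  norm <- stage("normalize",
                normalize_copy_number(bundle$otu_table, bundle$copy_numbers))
  gene_prof <- stage("impute", predict_metagenome(norm, bundle$gene_content))
  prof <- list(gene = gene_prof)
  for (lv in unique(c(cfg$levels, cfg$network_level))) {
    prof[[lv]] <- stage("collapse",
                        collapse_to_level(gene_prof, bundle$hierarchy, lv))
  }
  p <- file.path(cfg$out_dir, "profile_gene.tsv")
  write_profile(gene_prof, p); add("profile_gene", p)
  for (lv in setdiff(names(prof), "gene")) {
    p <- file.path(cfg$out_dir, sprintf("profile_%s.tsv", lv))
    write_profile(prof[[lv]], p); add(paste0("profile_", lv), p)
  }
  message("imputed ", ncol(gene_prof), " gene families over ",
          nrow(gene_prof), " samples")

  ## attribution (per gender)
  for (g in unique(meta$gender)) {
    ids <- meta$sample_id[meta$gender == g]
    tensor <- stage("attribution",
                    compute_contributions(norm[ids, , drop = FALSE],
                                          bundle$gene_content,
                                          bundle$taxonomy, bundle$hierarchy,
                                          rank = "phylum"))
    summ <- stage("attribution", summarize_attribution(tensor))
    tab <- data.frame(taxon = rep(rownames(summ$AAF), ncol(summ$AAF)),
                      category = rep(colnames(summ$AAF),
                                     each = nrow(summ$AAF)),
                      AAF = as.vector(summ$AAF), AAT = as.vector(summ$AAT),
                      TotalAA = rep(summ$TotalAA, ncol(summ$AAF)))
    p <- file.path(cfg$out_dir, sprintf("attribution_phylum_%s.tsv", g))
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    add(paste0("attribution_", g), p)
  }

  ## traits
  tp <- stage("traits", aggregate_traits(norm, bundle$traits))
  p <- file.path(cfg$out_dir, "trait_profile.tsv")
  write_profile(tp, p); add("trait_profile", p)
  ts <- stage("traits", group_trait_summary(tp, meta))
  p <- file.path(cfg$out_dir, "trait_summary.tsv")
  utils::write.table(ts, p, sep = "\t", quote = FALSE, row.names = FALSE)
  add("trait_summary", p)

  ## signatures, per gender stratum and level
  for (g in unique(meta$gender)) {
    ids <- meta$sample_id[meta$gender == g]
    grp <- meta$group[match(ids, meta$sample_id)]
    for (lv in cfg$levels) {
      x <- prof[[lv]][ids, , drop = FALSE]
      sig <- stage("lefse",
                   lefse(x, grp, alpha = cfg$kw_alpha, lda_min = cfg$lda_min,
                         mode = cfg$lefse_mode, seed = cfg$seed))
      p <- file.path(cfg$out_dir, sprintf("lefse_%s_%s.tsv", lv, g))
      utils::write.table(sig, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      add(sprintf("lefse_%s_%s", lv, g), p)
      message("lefse ", lv, "/", g, ": ", nrow(sig), " signatures")

      st <- stage("stamp", stamp_anova(x, grp, q_max = cfg$q_max))
      p <- file.path(cfg$out_dir, sprintf("stamp_%s_%s.tsv", lv, g))
      utils::write.table(st, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      add(sprintf("stamp_%s_%s", lv, g), p)
    }
    ## importance ranking on the gene-level profile
    filt <- stage("rf_filter",
                  filter_features(gene_prof[ids, , drop = FALSE],
                                  cfg$min_count, cfg$min_prevalence,
                                  cfg$variance_drop))
    message("rf filter ", g, ": ", ncol(filt), " of ", ncol(gene_prof),
            " features survive")
    css <- stage("rf_css", css_normalize(filt, cfg$css_quantile))
    rf <- stage("rf_rank", importance_rank(css, grp, n_top = cfg$rf_top,
                                           seed = cfg$seed))
    p <- file.path(cfg$out_dir, sprintf("rf_importance_%s.tsv", g))
    utils::write.table(rf$ranking, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add(sprintf("rf_importance_%s", g), p)
  }

  ## networks per group x gender
  metrics <- list()
  for (g in unique(meta$gender)) {
    for (grp in unique(meta$group[meta$gender == g])) {
      net <- stage("network",
                   suppressWarnings(
                     group_network(prof[[cfg$network_level]], meta, grp, g,
                                   B = cfg$network_B,
                                   alpha_edge = cfg$edge_alpha,
                                   seed = cfg$seed)))
      p <- file.path(cfg$out_dir, sprintf("network_%s_%s.tsv", grp, g))
      write_network(net, p)
      add(sprintf("network_%s_%s", grp, g), p)
      mm <- compute_metrics(net)
      mm$group <- grp; mm$gender <- g
      metrics[[length(metrics) + 1L]] <- mm
      hubs <- top_hubs(net, k = 10)
      p <- file.path(cfg$out_dir, sprintf("hubs_%s_%s.tsv", grp, g))
      utils::write.table(hubs, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      add(sprintf("hubs_%s_%s", grp, g), p)
    }
  }
  p <- file.path(cfg$out_dir, "network_metrics.tsv")
  utils::write.table(do.call(rbind, metrics), p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  add("network_metrics", p)

  manifest <- data.frame(artifact = names(paths), path = unname(paths),
                         md5 = unname(tools::md5sum(unname(paths))),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(cfg$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}
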