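# Shared builders and independent brute-force oracles.

# a small, fast cohort for property-style loops
small_config <- function(seed = 1L, ...) {
  cohort_config(group_sizes = list(F = c(Vata = 8, Pitta = 8, Kapha = 8)),
                n_otus = 60, n_functions = 60, n_pathways_l3 = 12,
                n_pathways_l2 = 5, sequencing_depth = 5000, seed = seed, ...)
}

# tiny named matrix helper
mat <- function(values, nrow, rnames, cnames) {
  matrix(values, nrow = nrow, byrow = TRUE,
         dimnames = list(rnames, cnames))
}

# triple-loop matrix product: the imputation oracle
bf_matmul <- function(a, b) {
  out <- matrix(0, nrow(a), ncol(b), dimnames = list(rownames(a),
                                                     colnames(b)))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(ncol(b)))
      for (k in seq_len(ncol(a)))
        out[i, j] <- out[i, j] + a[i, k] * b[k, j]
  out
}

# brute-force graph metrics from an adjacency matrix (0/1, symmetric):
# BFS all-pairs shortest paths on the largest component, triangle count,
# Freeman centralization -- independent of igraph
bf_metrics <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  keep <- deg > 0
  adj <- adj[keep, keep, drop = FALSE]
  n <- nrow(adj)
  e2 <- sum(adj)  # ordered-pair count
  if (n == 0) {
    return(list(nodes = 0, edges = 0, density = 0, diameter = 0,
                centralization = 0, clustering = 0))
  }
  deg <- rowSums(adj)
  bfs_dist <- function(src) {
    d <- rep(Inf, n); d[src] <- 0; frontier <- src
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) {
        nb <- which(adj[v, ] == 1 & d == Inf)
        d[nb] <- d[v] + 1
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
    d
  }
  # connected components via BFS
  comp <- rep(0L, n); cid <- 0L
  for (v in seq_len(n)) {
    if (comp[v] == 0L) {
      cid <- cid + 1L
      comp[is.finite(bfs_dist(v))] <- cid
    }
  }
  big <- which(comp == which.max(tabulate(comp)))
  diam <- 0
  for (v in big) {
    d <- bfs_dist(v)
    diam <- max(diam, max(d[is.finite(d)]))
  }
  tri <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i < j && j < k && adj[i, j] && adj[j, k] && adj[i, k]) tri <- tri + 1
  }
  triples <- sum(deg * (deg - 1) / 2)
  list(nodes = n, edges = e2, density = e2 / (n * (n - 1)),
       diameter = diam,
       centralization = if (n >= 3)
         sum(max(deg) - deg) / ((n - 1) * (n - 2)) else 0,
       clustering = if (triples > 0) 3 * tri / triples else 0)
}

# random symmetric 0/1 adjacency matrix without self-edges
random_adj <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  a + t(a)
}

adj_to_graph <- function(adj) {
  dimnames(adj) <- list(sprintf("N%02d", seq_len(nrow(adj))),
                        sprintf("N%02d", seq_len(nrow(adj))))
  r <- matrix(0.5, nrow(adj), ncol(adj), dimnames = dimnames(adj))
  p <- ifelse(adj == 1, 0.001, 0.5)
  diag(p) <- NA
  dimnames(p) <- dimnames(adj)
  build_network(r, p, alpha_edge = 0.01)
}

# impute a bundle down to a chosen level for one gender stratum
impute_stratum <- function(bundle, gender = "F", level = NULL) {
  norm <- normalize_copy_number(bundle$otu_table, bundle$copy_numbers)
  prof <- predict_metagenome(norm, bundle$gene_content)
  if (!is.null(level)) {
    prof <- suppressWarnings(collapse_to_level(prof, bundle$hierarchy, level))
  }
  ids <- bundle$metadata$sample_id[bundle$metadata$gender == gender]
  list(profile = prof[ids, , drop = FALSE],
       groups = bundle$metadata$group[match(ids, bundle$metadata$sample_id)])
}

# pathway-level planting design: pick n_per_group level-3 pathways per
# group (balanced total function load, no shared member functions) from a
# null bundle's hierarchy, and return the planted configuration plus truth
plant_pathways <- function(seed, fold = 8, n_per_group = 2) {
  b0 <- generate_cohort(cohort_config(seed = seed))
  h <- unique(b0$hierarchy[, c("function_id", "level3")])
  sizes <- sort(table(h$level3), decreasing = TRUE)
  cand <- names(sizes)[sizes >= 4 & sizes <= 12]
  groups <- c("Vata", "Pitta", "Kapha")
  sel <- stats::setNames(rep(list(character()), 3), groups)
  load <- stats::setNames(numeric(3), groups)
  used_funs <- character()
  for (p in cand) {
    if (all(lengths(sel) >= n_per_group)) break
    funs <- h$function_id[h$level3 == p]
    if (length(intersect(funs, used_funs))) next
    g <- names(which.min(ifelse(lengths(sel) >= n_per_group, Inf, load)))
    sel[[g]] <- c(sel[[g]], p)
    load[[g]] <- load[[g]] + length(funs)
    used_funs <- c(used_funs, funs)
  }
  pe <- lapply(groups, function(g)
    plant_effect(g, h$function_id[h$level3 %in% sel[[g]]], fold, "F"))
  truth <- stats::setNames(rep(groups, times = lengths(sel)), unlist(sel))
  contaminated <- setdiff(unique(h$level3[h$function_id %in% used_funs]),
                          names(truth))
  list(config = cohort_config(planted_effects = pe, seed = seed),
       truth = truth, contaminated = contaminated)
}

# score a signature table against a pathway-planting truth
score_recovery <- function(sig, truth, contaminated) {
  tp <- sum(sig$function_id %in% names(truth) &
              sig$enriched_group == truth[sig$function_id])
  fp <- sum(!(sig$function_id %in% c(names(truth), contaminated)) |
              (sig$function_id %in% names(truth) &
                 sig$enriched_group != truth[sig$function_id]))
  c(planted = length(truth), tp = tp, fp = fp)
}
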