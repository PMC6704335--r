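## Per-group functional co-occurrence networks: Pearson correlation,
## permutation-null p-values, p < alpha edge calling, topology metrics.
## Edge and degree counts are reported as ordered pairs (each undirected
## edge counted twice), the convention under which density is
## E / (N * (N - 1)).

#' Pearson correlation matrix over features of one group
#'
#' @param x samples x features matrix (samples of a single group).
#' @return symmetric correlation matrix with attribute `zero_variance`
#'   naming excluded constant features (their entries are `NA`).
#' @export
pearson_matrix <- function(x) {
  if (nrow(x) < 3) stop("need at least 3 samples to correlate")
  sds <- apply(x, 2, stats::sd)
  r <- suppressWarnings(stats::cor(x))
  zv <- colnames(x)[sds == 0]
  r[sds == 0, ] <- NA
  r[, sds == 0] <- NA
  attr(r, "zero_variance") <- zv
  r
}

#' Permutation-null p-values for pairwise correlations
#'
#' For each of `B` iterations every feature column is independently
#' shuffled across samples once, the full correlation matrix is
#' recomputed, and for every pair the exceedance of `|r_obs|` is counted.
#' The two-sided p-value is `(count + 1) / (B + 1)`, never exactly zero.
#' Zero-variance features get `p = 1` for all of their pairs; the
#' diagonal is `NA` (self-pairs are never tested).
#'
#' @param x samples x features matrix.
#' @param B number of permutations (>= 100).
#' @param seed integer seed.
#' @return list with `r` (observed correlations) and `p` (p-value matrix).
#' @export
permutation_pvalues <- function(x, B = 10000, seed = 1L) {
  if (B < 100) stop("B must be at least 100")
  set.seed(seed)
  n <- nrow(x); m <- ncol(x)
  sds <- apply(x, 2, stats::sd)
  r_obs <- suppressWarnings(stats::cor(x))
  a_obs <- abs(r_obs)
  count <- matrix(0, m, m)
  for (b in seq_len(B)) {
    xp <- x
    for (j in seq_len(m)) xp[, j] <- x[sample.int(n), j]
    rb <- suppressWarnings(stats::cor(xp))
    count <- count + (abs(rb) >= a_obs)
  }
  p <- (count + 1) / (B + 1)
  p[is.na(r_obs)] <- 1
  p[sds == 0, ] <- 1
  p[, sds == 0] <- 1
  diag(p) <- NA
  diag(r_obs)[is.na(diag(r_obs))] <- 1
  dimnames(p) <- dimnames(r_obs)
  list(r = r_obs, p = p)
}

#' Call edges and assemble the functional network
#'
#' Retains every unordered feature pair with `p < alpha_edge`; nodes are
#' the endpoints of at least one retained edge (isolated features are
#' dropped). Both correlation signs are kept, stored on the edges.
#'
#' @param r correlation matrix.
#' @param p p-value matrix.
#' @param alpha_edge edge-calling cutoff.
#' @return an undirected igraph graph with edge attributes `r` and `p`
#'   and graph attribute `alpha_edge`; empty (with a warning) when no
#'   edge survives.
#' @export
build_network <- function(r, p, alpha_edge = 0.01) {
  stopifnot(identical(dim(r), dim(p)))
  m <- nrow(r)
  ids <- colnames(r)
  if (is.null(ids)) ids <- as.character(seq_len(m))
  ut <- upper.tri(r)
  sel <- which(ut & !is.na(p) & p < alpha_edge, arr.ind = TRUE)
  if (!nrow(sel)) {
    warning("no edge passes the p < ", alpha_edge, " cutoff")
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    edges <- data.frame(from = ids[sel[, 1]], to = ids[sel[, 2]],
                        r = r[sel], p = p[sel], stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  }
  g <- igraph::set_graph_attr(g, "alpha_edge", alpha_edge)
  g
}

#' Graph density under the ordered-pair edge convention
#'
#' `density = edges / (nodes * (nodes - 1))` with `edges` counted as
#' ordered pairs (twice the number of undirected edges) — numerically the
#' standard undirected density.
#'
#' @param nodes node count.
#' @param edges ordered-pair edge count.
#' @return density (0 when `nodes < 2`).
#' @export
network_density <- function(nodes, edges) {
  if (nodes < 2) return(0)
  edges / (nodes * (nodes - 1))
}

#' Topology metrics of a functional network
#'
#' Reports node count, ordered-pair edge count, density, the diameter of
#' the largest connected component (unweighted shortest paths), Freeman
#' degree centralization `sum(d_max - d_i) / ((n - 1) * (n - 2))`, and the
#' global clustering coefficient (transitivity, 3 x triangles / connected
#' triples).
#'
#' @param net an igraph graph from [build_network()].
#' @return one-row data.frame with `nodes`, `edges`, `density`,
#'   `diameter`, `centralization`, `clustering_coefficient`.
#' @export
compute_metrics <- function(net) {
  n <- igraph::vcount(net)
  e2 <- 2L * igraph::ecount(net)
  if (n == 0) {
    return(data.frame(nodes = 0L, edges = 0L, density = 0, diameter = 0,
                      centralization = 0, clustering_coefficient = 0))
  }
  comp <- igraph::components(net)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(net, which(comp$membership == big))
  diam <- if (igraph::ecount(sub) > 0)
    igraph::diameter(sub, weights = NA) else 0
  # Freeman degree centralization, sum(d_max - d_i) / ((n-1)(n-2));
  # 1 for a star, 0 for any regular graph
  deg <- igraph::degree(net)
  centr <- if (n >= 3) sum(max(deg) - deg) / ((n - 1) * (n - 2)) else 0
  cc <- igraph::transitivity(net, type = "global")
  if (is.nan(cc)) cc <- 0
  data.frame(nodes = n, edges = e2, density = network_density(n, e2),
             diameter = diam, centralization = centr,
             clustering_coefficient = cc)
}

#' Top hub functions by degree
#'
#' @param net an igraph graph.
#' @param k number of hubs to report (all nodes if fewer).
#' @param annotations optional named character vector mapping function ids
#'   to description strings.
#' @return data.frame `function_id`, `degree` (ordered-pair count),
#'   `annotation`, sorted by descending degree with lexicographic
#'   tie-breaks.
#' @export
top_hubs <- function(net, k = 10, annotations = NULL) {
  if (igraph::vcount(net) == 0) {
    return(data.frame(function_id = character(), degree = integer(),
                      annotation = character(), stringsAsFactors = FALSE))
  }
  deg <- 2L * igraph::degree(net)
  nm <- igraph::V(net)$name
  if (is.null(nm)) nm <- as.character(seq_along(deg))
  ord <- order(-deg, nm)
  k <- min(k, length(deg))
  sel <- ord[seq_len(k)]
  ann <- if (is.null(annotations)) rep("", k) else {
    a <- annotations[nm[sel]]
    a[is.na(a)] <- ""
    unname(a)
  }
  data.frame(function_id = nm[sel], degree = unname(deg[sel]),
             annotation = ann, stringsAsFactors = FALSE)
}

#' Build one group's functional network end to end
#'
#' Convenience composition: subset the profile to the samples of one
#' (group, gender) stratum, correlate, permute, and call edges.
#'
#' @param profile samples x functions matrix.
#' @param metadata data.frame with `sample_id`, `group`, `gender`.
#' @param group,gender stratum selectors.
#' @param B permutations.
#' @param alpha_edge edge cutoff.
#' @param seed integer seed.
#' @return igraph graph with graph attributes `group` and `gender`.
#' @export
group_network <- function(profile, metadata, group, gender, B = 10000,
                          alpha_edge = 0.01, seed = 1L) {
  ids <- metadata$sample_id[metadata$group == group &
                              metadata$gender == gender]
  sub <- profile[intersect(rownames(profile), ids), , drop = FALSE]
  pv <- permutation_pvalues(sub, B = B, seed = seed)
  g <- build_network(pv$r, pv$p, alpha_edge = alpha_edge)
  g <- igraph::set_graph_attr(g, "group", group)
  igraph::set_graph_attr(g, "gender", gender)
}
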