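test_that("correlations match the textbook cases", {
  x <- cbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(6, 4, 2),
             d = c(1, 3, 2))
  r <- pearson_matrix(x)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(r["a", "d"], 0.5)
  expect_error(pearson_matrix(x[1:2, ]), "at least 3 samples")
  # constant features are flagged and excluded
  x2 <- cbind(x, e = c(7, 7, 7))
  r2 <- pearson_matrix(x2)
  expect_equal(attr(r2, "zero_variance"), "e")
  expect_true(all(is.na(r2["e", c("a", "b", "c", "d")])))
})

test_that("permutation p-values use add-one smoothing and skip self-pairs", {
  set.seed(14)
  x <- cbind(f1 = rnorm(20), f2 = 0)
  x[, "f2"] <- x[, "f1"]  # perfectly correlated pair
  pv <- permutation_pvalues(x, B = 199, seed = 1)
  expect_equal(pv$p["f1", "f2"], 1 / 200)  # (0 + 1) / (B + 1)
  expect_true(all(is.na(diag(pv$p))))
  # zero-variance features always get p = 1
  x2 <- cbind(x, f3 = rep(2, 20))
  pv2 <- permutation_pvalues(x2, B = 199, seed = 1)
  expect_equal(pv2$p["f3", "f1"], 1)
  expect_error(permutation_pvalues(x, B = 50), "at least 100")
})

test_that("permutation p-values are uniform under independence", {
  set.seed(15)
  x <- matrix(rnorm(40 * 30), 40, 30,
              dimnames = list(NULL, sprintf("f%02d", 1:30)))
  pv <- permutation_pvalues(x, B = 1000, seed = 1)
  p <- pv$p[upper.tri(pv$p)]
  ks <- max(abs(sort(p) - seq_along(p) / length(p)))
  expect_lt(ks, 0.05)
})

test_that("edge calling keeps significant pairs and drops isolates", {
  r <- matrix(0.9, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  p1 <- matrix(1, 3, 3, dimnames = dimnames(r)); diag(p1) <- NA
  expect_warning(g0 <- build_network(r, p1), "no edge")
  expect_equal(igraph::vcount(g0), 0)
  expect_equal(compute_metrics(g0)$nodes, 0)
  # one significant pair: two nodes, ordered-pair count 2
  p2 <- p1; p2["a", "b"] <- p2["b", "a"] <- 0.001
  g1 <- build_network(r, p2)
  m1 <- compute_metrics(g1)
  expect_equal(m1$nodes, 2)
  expect_equal(m1$edges, 2)
  # a triangle: 3 nodes, 6 ordered-pair edges, density 1
  p3 <- matrix(0.001, 3, 3, dimnames = dimnames(r)); diag(p3) <- NA
  g3 <- build_network(r, p3)
  m3 <- compute_metrics(g3)
  expect_equal(m3[, c("nodes", "edges", "density", "diameter",
                      "centralization", "clustering_coefficient")],
               data.frame(nodes = 3, edges = 6, density = 1, diameter = 1,
                          centralization = 0, clustering_coefficient = 1))
})

test_that("a three-node path has the textbook metrics", {
  r <- matrix(0.9, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  p <- matrix(1, 3, 3, dimnames = dimnames(r)); diag(p) <- NA
  p["a", "b"] <- p["b", "a"] <- 0.001
  p["b", "c"] <- p["c", "b"] <- 0.001
  m <- compute_metrics(build_network(r, p))
  expect_equal(m$density, 2 / 3)
  expect_equal(m$diameter, 2)
  expect_equal(m$centralization, 1)
  expect_equal(m$clustering_coefficient, 0)
})

test_that("metrics agree with the brute-force graph oracle", {
  for (seed in 1:6) {
    adj <- random_adj(n = 10 + 5 * seed, p = 0.12, seed = seed)
    bf <- bf_metrics(adj)
    m <- compute_metrics(adj_to_graph(adj))
    expect_equal(m$nodes, bf$nodes)
    expect_equal(m$edges, bf$edges)
    expect_equal(m$density, bf$density, tolerance = 1e-12)
    expect_equal(m$diameter, bf$diameter)
    expect_equal(m$centralization, bf$centralization, tolerance = 1e-12)
    expect_equal(m$clustering_coefficient, bf$clustering, tolerance = 1e-12)
  }
})

test_that("hub extraction orders by degree with lexicographic ties", {
  # star: center first
  r <- matrix(0.9, 4, 4, dimnames = list(c("z", "a", "b", "c"),
                                         c("z", "a", "b", "c")))
  p <- matrix(1, 4, 4, dimnames = dimnames(r)); diag(p) <- NA
  for (leaf in c("a", "b", "c")) p["z", leaf] <- p[leaf, "z"] <- 0.001
  g <- build_network(r, p)
  hubs <- top_hubs(g, k = 10, annotations = c(z = "center"))
  expect_equal(hubs$function_id[1], "z")
  expect_equal(hubs$degree[1], 6)
  expect_equal(hubs$annotation[1], "center")
  expect_equal(hubs$function_id[-1], c("a", "b", "c"))  # equal-degree ties
  # complete K4: all ordered-pair degrees 6
  p4 <- matrix(0.001, 4, 4, dimnames = dimnames(r)); diag(p4) <- NA
  h4 <- top_hubs(build_network(r, p4), k = 10)
  expect_equal(h4$degree, rep(6, 4))
})

test_that("stratum networks are deterministic under the seed", {
  b <- generate_cohort(small_config(seed = 17))
  st <- impute_stratum(b, "F", "L3")
  meta <- b$metadata
  g1 <- suppressWarnings(group_network(st$profile, meta, "Vata", "F",
                                       B = 200, seed = 3))
  g2 <- suppressWarnings(group_network(st$profile, meta, "Vata", "F",
                                       B = 200, seed = 3))
  expect_equal(igraph::as_data_frame(g1), igraph::as_data_frame(g2))
})
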