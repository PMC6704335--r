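test_that("the rank-test screen reproduces the hand-computed statistic", {
  # two groups {1,2} vs {3,4}: ranks 1,2 vs 3,4 ->
  # H = 12/(4*5) * (2*(1.5-2.5)^2 + 2*(3.5-2.5)^2) = 2.4
  prof <- mat(c(1, 2, 3, 4), 4, paste0("S", 1:4), "f1")
  out <- kruskal_screen(prof, c("a", "a", "b", "b"), alpha = 0.2)
  expect_equal(out$H, 2.4)
  # constant features are never candidates
  prof2 <- cbind(prof, f2 = c(5, 5, 5, 5))
  out2 <- kruskal_screen(prof2, c("a", "a", "b", "b"), alpha = 0.99)
  expect_equal(out2$p[out2$function_id == "f2"], 1)
  expect_false(out2$candidate[out2$function_id == "f2"])
  expect_error(kruskal_screen(prof, c("a", "a", "a", "a")), "two groups")
})

test_that("rank tests hold their nominal size on null features", {
  set.seed(31)
  g <- rep(c("V", "P", "K"), each = 15)
  prof <- matrix(rnorm(45 * 1000), 45, 1000,
                 dimnames = list(NULL, sprintf("f%04d", 1:1000)))
  kw <- kruskal_screen(prof, g, alpha = 0.05)
  expect_gt(mean(kw$candidate), 0.025)
  expect_lt(mean(kw$candidate), 0.075)
  an <- stamp_anova(prof, g, q_max = Inf)
  expect_gt(mean(an$anova_p < 0.05), 0.025)
  expect_lt(mean(an$anova_p < 0.05), 0.075)
})

test_that("pairwise consistency distinguishes strict and less-strict modes", {
  set.seed(5)
  g <- rep(c("A", "B", "C"), each = 8)
  # clearly separated top class passes both modes
  x <- c(rnorm(8, 10), rnorm(8, 0), rnorm(8, 0))
  ps <- pairwise_consistency(x, g, "strict")
  pl <- pairwise_consistency(x, g, "less-strict")
  expect_true(ps$pass); expect_true(pl$pass)
  expect_equal(ps$direction, "A")
  # A separates from B but overlaps C: one significant contrast only
  y <- c(c(2.1, 2.2, 2.3, 2.0, 1.9, 2.2, 2.1, 2.4),     # A, top mean
         c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8),     # B, clearly below
         c(3.5, 0.5, 3.0, 0.2, 2.8, 0.4, 2.6, 0.1))     # C, interleaved
  ys <- pairwise_consistency(y, g, "strict")
  yl <- pairwise_consistency(y, g, "less-strict")
  expect_false(ys$pass)
  expect_true(yl$pass)
})

test_that("LDA effect size matches the closed form for one feature", {
  set.seed(7)
  g <- rep(c("A", "B"), each = 12)
  x <- matrix(c(rnorm(12, 1000, 1), rnorm(12, 200, 1)), ncol = 1,
              dimnames = list(NULL, "f1"))
  es <- lda_effect_size(x, g, n_boot = 30, seed = 2)
  # single feature: unit coefficient, so each round score is the absolute
  # subsample class-mean difference; at sd 1 that is ~ the 800 gap
  expect_equal(unname(es), log10(1 + 800), tolerance = 0.01)
})

test_that("LDA effect size separates planted from flat features", {
  set.seed(8)
  g <- rep(c("A", "B"), each = 12)
  prof <- cbind(planted = c(rnorm(12, 1e5, 100), rnorm(12, 1e2, 100)),
                constant = rep(5e4, 24))
  es <- lda_effect_size(prof, g, seed = 3)
  expect_gte(es[["planted"]], 2)
  # a feature identical across classes carries no signal at all
  expect_equal(es[["constant"]], 0)
  # swapping the class labels flips direction but not the score (up to
  # the bootstrap resampling noise of the subsample draws)
  g2 <- ifelse(g == "A", "B", "A")
  expect_equal(lda_effect_size(prof, g2, seed = 3), es, tolerance = 0.05)
})

test_that("a planted pathway is emitted with the right enriched group", {
  pl <- plant_pathways(seed = 101, fold = 8)
  b <- generate_cohort(pl$config)
  st <- impute_stratum(b, "F", "L3")
  sig <- lefse(st$profile, st$groups, mode = "strict", seed = 1)
  kapha_paths <- names(pl$truth)[pl$truth == "Kapha"]
  hit <- sig[sig$function_id %in% kapha_paths, ]
  expect_gt(nrow(hit), 0)
  expect_true(all(hit$enriched_group == "Kapha"))
  expect_true(all(sig$lda_score >= 2))
})

test_that("strict signatures are a subset of less-strict signatures", {
  for (seed in 1:12) {
    b <- generate_cohort(small_config(seed = seed))
    st <- impute_stratum(b, "F")
    s_strict <- lefse(st$profile, st$groups, mode = "strict", seed = 1)
    s_less <- lefse(st$profile, st$groups, mode = "less-strict", seed = 1)
    expect_true(all(s_strict$function_id %in% s_less$function_id))
  }
})

test_that("a null cohort yields about the screening false-positive budget", {
  counts <- vapply(1:20, function(s) {
    b <- generate_cohort(cohort_config(seed = 300 + s))
    st <- impute_stratum(b, "F")
    nrow(lefse(st$profile, st$groups, mode = "less-strict", seed = 1))
  }, 0)
  budget <- 0.05 * 200
  expect_gt(mean(counts), 0.25 * budget)
  expect_lt(mean(counts), 2 * budget)
})

test_that("ANOVA effect sizes and corrections follow the definitions", {
  prof <- mat(c(1, 2, 3, 4), 4, paste0("S", 1:4), "f1")
  g <- c("a", "a", "b", "b")
  out <- stamp_anova(prof, g, q_max = Inf)
  expect_equal(out$eta_squared, 0.8)  # SSb 4 over SStot 5
  # BH across features is the step-up adjustment of the raw p's
  set.seed(9)
  prof2 <- matrix(rnorm(40 * 25,
                        mean = rep(c(0, 0.5), each = 20)), 40, 25,
                  dimnames = list(NULL, sprintf("f%02d", 1:25)))
  g2 <- rep(c("x", "y"), each = 20)
  res <- stamp_anova(prof2, g2, q_max = Inf)
  expect_equal(res$bh_q, p.adjust(res$anova_p, "BH"))
  # permutation of features leaves q-values attached to the same feature
  perm <- sample(25)
  res_p <- stamp_anova(prof2[, perm], g2, q_max = Inf)
  expect_equal(res_p$bh_q[match(res$function_id, res_p$function_id)],
               res$bh_q)
  # identically distributed constant groups are never significant
  prof3 <- mat(rep(1, 4), 4, paste0("S", 1:4), "f1")
  expect_equal(stamp_anova(prof3, g, q_max = Inf)$anova_p, 1)
})

test_that("Tukey-Kramer pairwise p-values accompany significant features", {
  set.seed(10)
  g <- rep(c("V", "P", "K"), times = c(8, 6, 10))
  prof <- cbind(up = c(rnorm(8, 6), rnorm(6, 0), rnorm(10, 0)),
                flat = rnorm(24))
  out <- stamp_anova(prof, g, q_max = 0.05)
  expect_true("up" %in% out$function_id)
  expect_false("flat" %in% out$function_id)
  tuk <- out[out$function_id == "up", grepl("tukey_", names(out))]
  expect_equal(sum(unlist(tuk) < 0.05), 2)  # V beats P and K; P~K flat
})

test_that("cumulative sum scaling matches the hand example", {
  prof <- mat(c(1, 2, 100), 1, "S1", c("f1", "f2", "f3"))
  out <- css_normalize(prof, quantile = 0.5)
  expect_equal(unname(out[1, ]), c(1, 2, 100) / 3 * 1000,
               tolerance = 1e-12)
  # identical samples scale identically; ranks are preserved
  prof2 <- rbind(S1 = c(4, 1, 9, 0), S2 = c(4, 1, 9, 0))
  colnames(prof2) <- paste0("f", 1:4)
  out2 <- css_normalize(prof2)
  expect_equal(out2["S1", ], out2["S2", ])
  expect_equal(order(out2["S1", ]), order(prof2["S1", ]))
  expect_error(css_normalize(rbind(S1 = c(0, 0))), "all zeros")
})

test_that("count, prevalence and variance filters follow the printed rules", {
  set.seed(11)
  prof <- matrix(rpois(4 * 12, 5), 4, 12,
                 dimnames = list(paste0("S", 1:4), sprintf("f%02d", 1:12)))
  prof[, "f01"] <- 0                      # all-zero: removed
  prof[, "f02"] <- c(3, 0, 0, 0)          # >=2 in 1/4 = 25% >= 20%: kept
  out <- filter_features(prof, min_count = 2, min_prevalence = 0.20,
                         variance_drop_fraction = 0)
  expect_false("f01" %in% colnames(out))
  expect_true("f02" %in% colnames(out))
  # floor rule: 10 survivors lose exactly one feature at 10%
  prof2 <- matrix(rpois(6 * 10, 20), 6, 10,
                  dimnames = list(paste0("S", 1:6), sprintf("g%02d", 1:10)))
  out2 <- filter_features(prof2, min_count = 0, min_prevalence = 0,
                          variance_drop_fraction = 0.10)
  expect_equal(ncol(out2), 9)
  iqr <- apply(prof2, 2, IQR)
  expect_false(names(which.min(iqr)) %in% colnames(out2))
  expect_error(filter_features(matrix(0, 3, 2), min_count = 2,
                               min_prevalence = 0.5),
               "no feature passes")
})

test_that("forest importance ranks a separating feature first", {
  set.seed(12)
  g <- rep(c("V", "P", "K"), each = 15)
  prof <- matrix(rnorm(45 * 30), 45, 30,
                 dimnames = list(NULL, sprintf("f%02d", 1:30)))
  prof[, "f07"] <- c(rnorm(15, 0), rnorm(15, 5), rnorm(15, 10))
  out <- importance_rank(prof, g, n_top = 50, seed = 4)
  expect_equal(out$ranking$function_id[1], "f07")
  expect_equal(nrow(out$ranking), 30)  # n_top above m reports all
  # determinism under the seed
  out2 <- importance_rank(prof, g, n_top = 50, seed = 4)
  expect_identical(out$ranking, out2$ranking)
})

test_that("out-of-bag error sits at chance level for shuffled labels", {
  set.seed(13)
  g <- sample(rep(c("V", "P", "K"), each = 15))
  prof <- matrix(rnorm(45 * 30), 45, 30,
                 dimnames = list(NULL, sprintf("f%02d", 1:30)))
  out <- importance_rank(prof, g, seed = 5)
  expect_lt(abs(out$oob_error - (1 - 1 / 3)), 0.15)
})
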