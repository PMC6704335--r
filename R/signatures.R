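## Three signature-discovery routes over predicted function profiles:
##  1. rank-test screen + pairwise consistency + bootstrapped LDA effect
##     size (strict / less-strict multi-class modes, log-LDA threshold);
##  2. per-feature one-way ANOVA with Tukey-Kramer post hoc tests,
##     eta-squared effect sizes and Benjamini-Hochberg correction;
##  3. random-forest importance ranking after low-count / low-variance
##     filtering and cumulative sum scaling.

#' Kruskal-Wallis screen over features
#'
#' Runs the midrank Kruskal-Wallis test (tie-corrected H) feature by
#' feature and keeps candidates with `p < alpha`. Constant features get
#' `p = 1` and are never candidates.
#'
#' @param profile samples x features matrix.
#' @param groups factor/character vector of class labels per sample.
#' @param alpha screening level.
#' @return data.frame with `function_id`, `H`, `p`, `candidate`.
#' @export
kruskal_screen <- function(profile, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  res <- apply(profile, 2, function(x) {
    if (stats::var(x) == 0) return(c(H = 0, p = 1))
    kt <- stats::kruskal.test(x, groups)
    c(H = unname(kt$statistic), p = kt$p.value)
  })
  out <- data.frame(function_id = colnames(profile),
                    H = res["H", ], p = res["p", ],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$candidate <- out$p < alpha
  out
}

#' Pairwise rank-test consistency of a candidate feature
#'
#' Identifies the top-mean class and tests it against every other class
#' with two-sided Wilcoxon rank-sum tests (midranks, normal
#' approximation). In `strict` mode every comparison must be significant
#' with the top class larger; in `less-strict` mode one such comparison
#' suffices.
#'
#' @param x numeric feature values.
#' @param groups class labels.
#' @param mode `"strict"` (all-against-all) or `"less-strict"`
#'   (one-against-all).
#' @param alpha per-comparison level.
#' @return list with `pass`, `direction` (the top-mean class) and the
#'   vector `p` of pairwise p-values.
#' @export
pairwise_consistency <- function(x, groups, mode = c("strict", "less-strict"),
                                 alpha = 0.05) {
  mode <- match.arg(mode)
  groups <- factor(groups)
  means <- tapply(x, groups, mean)
  top <- names(means)[order(-means, names(means))][1]
  others <- setdiff(levels(groups), top)
  p <- vapply(others, function(o) {
    suppressWarnings(stats::wilcox.test(x[groups == top], x[groups == o],
                                        exact = FALSE)$p.value)
  }, 0)
  ok <- !is.na(p) & p < alpha &
    vapply(others, function(o) means[[top]] > means[[o]], TRUE)
  pass <- if (mode == "strict") all(ok) else any(ok)
  list(pass = pass, direction = top, p = p)
}

#' Bootstrapped linear-discriminant effect size
#'
#' For each of `n_boot` rounds, subsamples two thirds of every class, fits
#' a linear discriminant on the class labels, and scores every feature by
#' half the sum of (i) the absolute class-mean difference of the feature
#' and (ii) the absolute class-mean difference of the discriminant scores
#' projected back through the feature's (unit-normalized) discriminant
#' coefficient. Multi-class inputs take the maximum over class pairs. The
#' reported effect size is `log10(1 + mean round score)`; features should
#' be on a per-million relative-abundance scale so that the conventional
#' threshold of 2.0 is meaningful.
#'
#' @param profile samples x features matrix (per-million scale).
#' @param groups class labels.
#' @param n_boot bootstrap rounds.
#' @param seed integer seed for the subsampling.
#' @return named vector of log10 effect sizes.
#' @export
lda_effect_size <- function(profile, groups, n_boot = 30, seed = 1L) {
  groups <- factor(groups)
  cls <- levels(groups)
  if (length(cls) < 2) stop("need at least two classes")
  set.seed(seed)
  m <- ncol(profile)
  acc <- numeric(m)
  used <- 0L
  skipped <- 0L
  pairs <- utils::combn(cls, 2, simplify = FALSE)
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(cls, function(cl) {
      i <- which(groups == cl)
      sample(i, max(2L, floor(2 / 3 * length(i))))
    }))
    sub <- profile[idx, , drop = FALSE]
    g <- droplevels(groups[idx])
    if (nlevels(g) < 2) { skipped <- skipped + 1L; next }
    # features constant within every class break the discriminant fit;
    # they enter the raw-mean term with a zero coefficient
    sds <- vapply(seq_len(m), function(j)
      max(tapply(sub[, j], g, stats::sd)), 0)
    fit_cols <- which(sds > 0)
    w_unit <- numeric(m)
    ld <- NULL
    if (length(fit_cols) >= 1) {
      fit <- tryCatch(
        MASS::lda(sub[, fit_cols, drop = FALSE], grouping = g),
        error = function(e) NULL)
      if (!is.null(fit)) {
        w <- fit$scaling[, 1]
        nw <- sqrt(sum(w^2))
        if (nw > 0) {
          w_unit[fit_cols] <- w / nw
          ld <- sub[, fit_cols, drop = FALSE] %*% (w / nw)
        }
      }
    }
    if (is.null(ld)) { skipped <- skipped + 1L; next }
    cm <- matrix(vapply(levels(g), function(cl)
      colMeans(sub[g == cl, , drop = FALSE]), numeric(m)),
      nrow = m, dimnames = list(colnames(sub), levels(g)))
    ldm <- tapply(ld[, 1], g, mean)
    round_score <- numeric(m)
    for (pr in pairs) {
      if (!all(pr %in% levels(g))) next
      gm <- abs(cm[, pr[1]] - cm[, pr[2]])
      coeff <- abs(w_unit * (ldm[[pr[1]]] - ldm[[pr[2]]]))
      round_score <- pmax(round_score, 0.5 * (gm + coeff))
    }
    acc <- acc + round_score
    used <- used + 1L
  }
  if (skipped) message(skipped, " bootstrap round(s) skipped")
  if (!used) stop("no usable bootstrap round")
  stats::setNames(log10(1 + acc / used), colnames(profile))
}

#' Multi-class biomarker discovery with LDA effect sizes
#'
#' Composition of [kruskal_screen()], [pairwise_consistency()] and
#' [lda_effect_size()]: features are rescaled per sample to a per-million
#' relative abundance, screened at `alpha`, checked for pairwise
#' directional consistency under the chosen mode, and retained when the
#' log-LDA effect size reaches `lda_min`. Effect sizes are computed once
#' on the screened set, so strict results are always a subset of
#' less-strict results on the same input and seed.
#'
#' @param profile samples x features matrix (counts or abundances).
#' @param groups class labels per sample.
#' @param alpha screening level for the rank tests.
#' @param lda_min minimum log10 LDA score for an emitted record.
#' @param mode `"strict"` or `"less-strict"`.
#' @param n_boot,seed passed to [lda_effect_size()].
#' @param rescale set `FALSE` if `profile` is already per-million.
#' @return data.frame of signature records (`function_id`,
#'   `enriched_group`, `kw_p`, `lda_score`, `mode`), sorted by descending
#'   score.
#' @export
lefse <- function(profile, groups, alpha = 0.05, lda_min = 2.0,
                  mode = c("strict", "less-strict"), n_boot = 30,
                  seed = 1L, rescale = TRUE) {
  mode <- match.arg(mode)
  groups <- factor(groups)
  if (rescale) {
    tot <- rowSums(profile)
    if (any(tot <= 0)) stop("sample(s) with zero total abundance")
    profile <- profile / tot * 1e6
  }
  screen <- kruskal_screen(profile, groups, alpha)
  cand <- screen$function_id[screen$candidate]
  empty <- data.frame(function_id = character(), enriched_group = character(),
                      kw_p = numeric(), lda_score = numeric(),
                      mode = character(), stringsAsFactors = FALSE)
  if (!length(cand)) return(empty)
  scores <- lda_effect_size(profile[, cand, drop = FALSE], groups,
                            n_boot = n_boot, seed = seed)
  keep <- list()
  for (f in cand) {
    pc <- pairwise_consistency(profile[, f], groups, mode = mode,
                               alpha = alpha)
    if (pc$pass && scores[[f]] >= lda_min) {
      keep[[f]] <- data.frame(function_id = f, enriched_group = pc$direction,
                              kw_p = screen$p[screen$function_id == f],
                              lda_score = scores[[f]], mode = mode,
                              stringsAsFactors = FALSE)
    }
  }
  if (!length(keep)) return(empty)
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out[order(-out$lda_score, out$function_id), , drop = FALSE]
}

#' Per-feature ANOVA with Tukey-Kramer post hoc tests
#'
#' One-way fixed-effects ANOVA per feature with eta-squared
#' (`SS_between / SS_total`) effect sizes, Tukey-Kramer studentized-range
#' pairwise p-values (unequal group sizes allowed), and
#' Benjamini-Hochberg correction across features.
#'
#' @param profile samples x features matrix.
#' @param groups class labels.
#' @param q_max retain features with `bh_q <= q_max`; set `Inf` to return
#'   everything.
#' @return data.frame with `function_id`, `anova_p`, `eta_squared`,
#'   `bh_q`, `significant`, plus one `tukey_*` column per class pair;
#'   rows filtered to `bh_q <= q_max`.
#' @export
stamp_anova <- function(profile, groups, q_max = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  rows <- lapply(colnames(profile), function(f) {
    x <- profile[, f]
    if (stats::var(x) == 0) {
      return(data.frame(function_id = f, anova_p = 1, eta_squared = 0,
                        stringsAsFactors = FALSE))
    }
    fit <- stats::aov(x ~ groups)
    tab <- summary(fit)[[1]]
    ss_b <- tab["groups", "Sum Sq"]
    ss_tot <- sum(tab[, "Sum Sq"])
    p <- tab["groups", "Pr(>F)"]
    if (!is.na(p) && p == 0) p <- 1e-300  # underflow floor
    tk <- stats::TukeyHSD(fit)$groups[, "p adj"]
    out <- data.frame(function_id = f, anova_p = p,
                      eta_squared = ss_b / ss_tot,
                      stringsAsFactors = FALSE)
    for (nm in names(tk)) out[[paste0("tukey_", gsub("-", "_vs_", nm))]] <-
      tk[[nm]]
    out
  })
  # features skipped as constant have no tukey columns; fill with NA
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(all_cols, names(r))) r[[nm]] <- NA_real_
    r[all_cols]
  })
  out <- do.call(rbind, rows)
  out$bh_q <- stats::p.adjust(out$anova_p, method = "BH")
  out$significant <- out$bh_q <= q_max
  out[out$bh_q <= q_max | is.infinite(q_max), , drop = FALSE]
}

#' Cumulative sum scaling
#'
#' Per sample, the scaling factor is the sum of all counts less than or
#' equal to the chosen quantile of that sample's nonzero counts; each
#' value is divided by the factor and multiplied by `scale`. Zeros are
#' preserved and within-sample rank order is unchanged.
#'
#' @param profile samples x features non-negative matrix.
#' @param quantile quantile of the nonzero counts (default median).
#' @param scale output scale (1000 by convention).
#' @return scaled matrix.
#' @export
css_normalize <- function(profile, quantile = 0.5, scale = 1000) {
  out <- profile
  for (s in seq_len(nrow(profile))) {
    x <- profile[s, ]
    nz <- x[x > 0]
    if (!length(nz)) stop("sample ", rownames(profile)[s], " is all zeros")
    q <- stats::quantile(nz, quantile, names = FALSE)
    factor <- sum(x[x <= q])
    if (factor == 0) factor <- sum(x)
    out[s, ] <- x / factor * scale
  }
  out
}

#' Low-count and low-variance feature filtering
#'
#' Keeps features with a count of at least `min_count` in at least a
#' `min_prevalence` fraction of samples, then removes the
#' `variance_drop_fraction` of survivors with the smallest inter-quartile
#' range (`floor(fraction * m)` features; ties resolved by input order).
#'
#' @param profile samples x features matrix.
#' @param min_count minimum count.
#' @param min_prevalence minimum fraction of samples at `min_count`.
#' @param variance_drop_fraction fraction of surviving features dropped by
#'   smallest IQR.
#' @return filtered matrix.
#' @export
filter_features <- function(profile, min_count = 2, min_prevalence = 0.20,
                            variance_drop_fraction = 0.10) {
  prev <- colMeans(profile >= min_count)
  keep <- prev >= min_prevalence
  if (!any(keep)) stop("no feature passes the count/prevalence filter")
  out <- profile[, keep, drop = FALSE]
  n_drop <- floor(variance_drop_fraction * ncol(out))
  if (n_drop > 0) {
    iqr <- apply(out, 2, stats::IQR)
    drop_idx <- order(iqr)[seq_len(n_drop)]
    out <- out[, -drop_idx, drop = FALSE]
  }
  if (!ncol(out)) stop("all features removed by the variance filter")
  out
}

#' Random-forest importance ranking
#'
#' Fits an ensemble of classification trees on the (filtered, scaled)
#' profile and ranks features by mean decrease in out-of-bag accuracy
#' under per-feature permutation. The ranking is a stable sort on the
#' score with lexicographic tie-breaks.
#'
#' @param profile samples x features matrix (already filtered and
#'   CSS-scaled).
#' @param groups class labels.
#' @param n_top number of top features to report (all if fewer survive).
#' @param n_trees number of trees.
#' @param seed integer seed.
#' @return list with `ranking` (data.frame `function_id`, `importance`,
#'   `rank`), `oob_error` (final out-of-bag error rate) and `err_curve`
#'   (per-tree OOB error).
#' @export
importance_rank <- function(profile, groups, n_top = 30, n_trees = 500,
                            seed = 1L) {
  groups <- factor(groups)
  set.seed(seed)
  rf <- randomForest::randomForest(x = as.data.frame(profile), y = groups,
                                   ntree = n_trees, importance = TRUE)
  imp <- randomForest::importance(rf, type = 1)[, 1]
  names(imp) <- colnames(profile)
  ord <- order(-imp, names(imp))
  n_top <- min(n_top, length(imp))
  ranking <- data.frame(function_id = names(imp)[ord][seq_len(n_top)],
                        importance = unname(imp[ord])[seq_len(n_top)],
                        rank = seq_len(n_top), stringsAsFactors = FALSE)
  err <- rf$err.rate[, "OOB"]
  list(ranking = ranking, oob_error = unname(err[length(err)]),
       err_curve = unname(err))
}
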