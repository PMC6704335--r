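test_that("copy-number normalization divides elementwise", {
  x <- mat(c(10, 4, 8, 2, 6, 0), 2, c("S1", "S2"), c("A", "B", "C"))
  expect_equal(normalize_copy_number(x, c(A = 1, B = 1, C = 1)), x)
  expect_equal(normalize_copy_number(x, c(A = 2, B = 1, C = 1))["S1", "A"], 5)
  cp <- c(A = 1, B = 2, C = 4)
  out <- normalize_copy_number(x, cp)
  for (s in rownames(x)) for (o in colnames(x)) {
    expect_equal(out[s, o], x[s, o] / cp[[o]])
  }
  expect_error(normalize_copy_number(x, c(A = 0, B = 1, C = 1)),
               "non-positive")
  expect_warning(normalize_copy_number(x, c(A = 2, B = 2)),
                 "without 16S copy number")
})

test_that("metagenome prediction is the gene-content-weighted sum", {
  norm <- mat(c(2, 3), 1, "S1", c("O1", "O2"))
  gc <- mat(c(1, 2, 0, 1), 2, c("O1", "O2"), c("KO1", "KO2"))
  expect_equal(predict_metagenome(norm, gc),
               mat(c(2, 7), 1, "S1", c("KO1", "KO2")), ignore_attr = TRUE)
  # one OTU with a unit gene vector transports its abundance unchanged
  gc2 <- mat(c(0, 1), 1, "O1", c("KO1", "KO2"))
  expect_equal(predict_metagenome(mat(5, 1, "S1", "O1"), gc2)[1, ],
               c(KO1 = 0, KO2 = 5))
  # linearity
  expect_equal(predict_metagenome(2 * norm, gc),
               2 * predict_metagenome(norm, gc), ignore_attr = TRUE)
  expect_error(predict_metagenome(mat(1, 1, "S1", "O9"), gc), "O9")
})

test_that("prediction matches the triple-loop oracle on random instances", {
  for (seed in 1:3) {
    set.seed(seed)
    norm <- matrix(runif(6 * 5), 6, 5,
                   dimnames = list(paste0("S", 1:6), paste0("O", 1:5)))
    gc <- matrix(rpois(5 * 4, 2), 5, 4,
                 dimnames = list(paste0("O", 1:5), paste0("K", 1:4)))
    expect_equal(predict_metagenome(norm, gc), bf_matmul(norm, gc),
                 ignore_attr = TRUE)
  }
})

test_that("pathway collapse counts multi-mapped families fully in each", {
  h <- data.frame(function_id = c("KO1", "KO2", "KO2"),
                  level3 = c("P1", "P1", "P2"),
                  level2 = c("Q1", "Q1", "Q1"),
                  level1 = rep("Metabolism", 3))
  prof <- mat(c(2, 7), 1, "S1", c("KO1", "KO2"))
  l3 <- collapse_to_level(prof, h, "L3")
  expect_equal(l3[1, ], c(P1 = 9, P2 = 7))
  # with multi-mapping, total mass can only grow
  expect_gte(sum(l3), sum(prof))
  # a one-to-one map conserves column mass
  h1 <- data.frame(function_id = c("KO1", "KO2"), level3 = c("P1", "P2"),
                   level2 = "Q1", level1 = "Metabolism")
  expect_equal(sum(collapse_to_level(prof, h1, "L3")), sum(prof))
  # unknown functions are dropped with a warning that counts them
  expect_warning(out <- collapse_to_level(
    mat(c(1, 2), 1, "S1", c("KO1", "KOX")), h1, "L3"),
    "1 function")
  expect_equal(colnames(out), "P1")
  expect_equal(out[1, "P1"], 1)
  expect_warning(empty <- collapse_to_level(prof,
                                            h1[0, , drop = FALSE], "L3"),
                 "2 function")
  expect_equal(ncol(empty), 0)
})

test_that("the imputation pipeline is scale-equivariant per sample", {
  b <- generate_cohort(small_config(seed = 6))
  norm <- normalize_copy_number(b$otu_table, b$copy_numbers)
  norm2 <- norm
  norm2["S001", ] <- 3 * norm2["S001", ]
  p1 <- predict_metagenome(norm, b$gene_content)
  p2 <- predict_metagenome(norm2, b$gene_content)
  expect_equal(p2["S001", ], 3 * p1["S001", ])
  expect_equal(p2["S002", ], p1["S002", ])
  l1 <- collapse_to_level(p1, b$hierarchy, "L2")
  l2 <- collapse_to_level(p2, b$hierarchy, "L2")
  expect_equal(l2["S001", ], 3 * l1["S001", ])
})

test_that("set analysis enumerates every intersection region", {
  mk <- function(funs, all_funs) {
    m <- matrix(0, 1, length(all_funs), dimnames = list("S", all_funs))
    m[1, funs] <- 1
    m
  }
  u <- c("A", "B", "C", "D")
  v <- venn_functions(list(V = mk(c("A", "B", "C"), u),
                           P = mk(c("B", "C"), u),
                           K = mk(c("B", "D"), u)))
  expect_equal(v$common, 1)                      # B only
  expect_equal(v$regions[["V&P"]], 1)            # C
  expect_equal(v$regions[["V"]], 1)              # A
  expect_equal(v$regions[["K"]], 1)              # D
  # identical sets: everything common
  v2 <- venn_functions(list(a = mk(c("A", "B"), u), b = mk(c("A", "B"), u)))
  expect_equal(v2$common, 2)
  # disjoint sets: nothing common
  v3 <- venn_functions(list(a = mk("A", u), b = mk("B", u)))
  expect_equal(v3$common, 0)
  expect_error(venn_functions(list(a = mk("A", u))), "two groups")
})
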