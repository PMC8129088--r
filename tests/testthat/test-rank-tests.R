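test_that("Wilcoxon worked example and degenerate cases", {
  res <- wilcoxonRankSum(c(5, 6, 7), c(1, 2, 3))
  expect_true(res$exact)
  expect_equal(res$p.value, 0.1, tolerance = 1e-12)   # 2 * 1/20 enumerations
  expect_equal(enumWilcoxP(c(5, 6, 7), c(1, 2, 3)), 0.1)

  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(3, 2, 1))$p.value, 1)
  expect_equal(wilcoxonRankSum(rep(2, 5), rep(2, 3))$p.value, 1)
  expect_error(wilcoxonRankSum(numeric(0), 1:3), "non-empty")
})

test_that("exact Wilcoxon branch equals exhaustive enumeration", {
  for (n in c(6, 8)) {
    for (m in 1:(n - 1)) {
      sub <- utils::combn(n, m)
      for (j in seq_len(ncol(sub))) {
        x <- sub[, j]; y <- setdiff(seq_len(n), x)
        expect_equal(wilcoxonRankSum(x, y)$p.value, enumWilcoxP(x, y),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("normal-approximation branch tracks the exact branch", {
  # deterministic sweep at pooled n = 12; the tie-corrected continuity-
  # corrected approximation is within 0.02 of exact for groups of >= 4
  maxd <- 0
  for (m in 4:8) {
    sub <- utils::combn(12, m)
    for (j in seq_len(ncol(sub))) {
      x <- sub[, j]; y <- setdiff(1:12, x)
      pe <- wilcoxonRankSum(x, y)$p.value       # exact branch (n <= 12)
      pa <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                correct = TRUE)$p.value)
      maxd <- max(maxd, abs(pe - pa))
    }
  }
  expect_lt(maxd, 0.02)
})

test_that("Kruskal-Wallis worked example and degenerate cases", {
  res <- kruskalWallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(round(res$statistic, 4), 4.5714)
  expect_equal(round(res$p.value, 4), 0.1017)
  expect_equal(res$p.value, exp(-res$statistic / 2), tolerance = 1e-12) # df = 2
  expect_equal(kruskalWallis(list(1:3, 1:3, 1:3))$p.value, 1)
  expect_equal(kruskalWallis(list(c(2, 2), c(2, 2), c(2, 2)))$p.value, 1)
  expect_equal(kruskalWallis(list(c(2, 2), c(2, 2)))$statistic, 0)
  expect_error(kruskalWallis(list(1:3)), "two groups")
  expect_error(kruskalWallis(list(1:3, numeric(0))), "empty group")
})

test_that("two-group Kruskal-Wallis equals the tie-corrected Wilcoxon", {
  set.seed(5)
  for (i in 1:20) {
    x <- rpois(15, 3); y <- rpois(18, 4)   # heavy ties
    pk <- kruskalWallis(list(x, y))$p.value
    pw <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = FALSE)$p.value)
    expect_equal(pk, pw, tolerance = 1e-9)
  }
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroniAdjust(0.004, 10), 0.04)
  expect_equal(bonferroniAdjust(0.2, 10), 1)
  expect_equal(bonferroniAdjust(c(0.3, 0.01)), c(0.6, 0.02))
  expect_identical(bonferroniAdjust(0.37, 1), 0.37)
  expect_error(bonferroniAdjust(c(0.1, 0.2), 1), ">=")
})

test_that("row-wise batch tests agree with the stats oracles", {
  set.seed(9)
  mat <- matrix(rnbinom(50 * 60, mu = 2, size = 1), nrow = 50)
  g3 <- factor(rep(c("a", "b", "c"), each = 20))
  batch <- scSegDEG:::.rowKruskal(mat, g3)
  for (i in c(1, 7, 23, 50)) {
    kt <- stats::kruskal.test(mat[i, ], g3)
    if (length(unique(mat[i, ])) == 1L) {
      expect_equal(batch$p[i], 1)
    } else {
      expect_equal(batch$H[i], unname(kt$statistic), tolerance = 1e-10)
      expect_equal(batch$p[i], unname(kt$p.value), tolerance = 1e-10)
    }
  }
  idx1 <- 1:25
  bw <- scSegDEG:::.rowWilcoxon(mat, idx1)
  for (i in c(2, 11, 37)) {
    wt <- suppressWarnings(stats::wilcox.test(mat[i, idx1], mat[i, -idx1],
                                              exact = FALSE, correct = TRUE))
    if (length(unique(mat[i, ])) == 1L) {
      expect_equal(bw$p[i], 1)
    } else {
      expect_equal(bw$W[i], unname(wt$statistic), tolerance = 1e-10)
      expect_equal(bw$p[i], unname(wt$p.value), tolerance = 1e-10)
    }
  }
})
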