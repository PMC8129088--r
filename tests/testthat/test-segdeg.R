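test_that("expressing proportion is strict at the 25% rule", {
  expect_equal(expressingProportion(c(rep(1, 3), rep(0, 9))), 0.25)
  expect_false(expressingProportion(c(rep(1, 3), rep(0, 9))) > 0.25)
  expect_true(expressingProportion(c(rep(1, 4), rep(0, 8))) > 0.25)
  expect_equal(expressingProportion(rep(0, 7)), 0)
  expect_error(expressingProportion(numeric(0)), "empty")
})

test_that("segment fold change identifies extremes on the RPM scale", {
  fc <- segmentFoldChange(c(caput = 1000, corpus = 0, cauda = 10))
  expect_equal(fc$high_segment, "caput")
  expect_equal(fc$low_segment, "corpus")
  expect_equal(fc$fold_change, log(1001), tolerance = 1e-12)
  expect_equal(round(fc$fold_change, 4), 6.9088)

  eq <- segmentFoldChange(c(caput = 5, corpus = 5, cauda = 5))
  expect_equal(eq$fold_change, 0)

  # a fold change of exactly 2 fails the strict "> 2" rule
  boundary <- segmentFoldChange(c(caput = exp(2) * (1 + 0) - 1, corpus = 0))
  expect_equal(boundary$fold_change, 2, tolerance = 1e-12)
  expect_false(boundary$fold_change > 2)
})

test_that("planted segmental effects are recovered with correct labels", {
  des <- tinyDesign(
    cellsPerSegment = 160L,
    segmentalEffectSpec = data.frame(
      gene_id = NA, cluster = "principal", segment = "caput",
      effect = 3, detect_target = 0.4))
  x <- computeLog1pRPM(simulateDataset(des, seed = 13))
  res <- suppressWarnings(callSegmentalDegs(x))
  g <- groundTruth(x)$segmental$gene_id
  hit <- res[res$gene_id == g & res$cluster == "principal", ]
  expect_true(hit$retained_specific)
  expect_equal(hit$high_segment, "caput")
  expect_true(hit$min_fold_change > 2)
  expect_true(hit$min_best_prop > 0.25)
  expect_lt(hit$combined_p_adj, 0.05)
})

test_that("genes passing in two clusters are dropped by the specificity rule", {
  des <- tinyDesign(cellsPerSegment = 160L)
  sp <- data.frame(gene_id = c("gene00050", "gene00050"),
                   cluster = c("principal", "basal"),
                   segment = "caput", effect = 3, detect_target = 0.4)
  x <- computeLog1pRPM(simulateDataset(tinyDesign(
    cellsPerSegment = 160L, segmentalEffectSpec = sp), seed = 17))
  res <- suppressWarnings(callSegmentalDegs(x))
  rows <- res[res$gene_id == "gene00050", ]
  expect_equal(sum(rows$passes_all), 2)
  expect_false(any(rows$retained_specific))
})

test_that("segmental calls are invariant to cell and gene ordering", {
  des <- tinyDesign(segmentalEffectSpec = data.frame(
    gene_id = NA, cluster = "basal", segment = "cauda",
    effect = 3, detect_target = 0.5))
  x <- computeLog1pRPM(simulateDataset(des, seed = 23))
  res1 <- suppressWarnings(callSegmentalDegs(x))
  set.seed(1)
  xp <- x[sample(nrow(x)), sample(ncol(x))]
  res2 <- suppressWarnings(callSegmentalDegs(xp))
  key <- function(r) {
    r <- r[order(r$gene_id, r$cluster), ]
    r[, c("gene_id", "cluster", "combined_p_adj", "min_fold_change",
          "passes_all", "retained_specific")]
  }
  expect_equal(key(res1), key(res2), ignore_attr = TRUE)
})

test_that("samples without two testable segments are skipped with warning", {
  x <- computeLog1pRPM(simulateDataset(tinyDesign(), seed = 3))
  keep <- !(cellSamples(x) == "P42_1" &
              as.character(cellSegments(x)) != "caput")
  x1 <- x[, keep]
  expect_warning(res <- callSegmentalDegs(x1, clusters = "principal"),
                 "P42_1")
  expect_true(all(is.na(res$p_adj_P42_1)))
})
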