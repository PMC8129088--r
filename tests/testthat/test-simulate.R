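test_that("the generator is deterministic given the seed", {
  a <- simulateDataset(tinyDesign(), seed = 5)
  b <- simulateDataset(tinyDesign(), seed = 5)
  expect_identical(as.matrix(umiCounts(a)), as.matrix(umiCounts(b)))
  expect_identical(colnames(a), colnames(b))
  expect_identical(groundTruth(a)$segmental, groundTruth(b)$segmental)
  c <- simulateDataset(tinyDesign(), seed = 6)
  expect_false(identical(as.matrix(umiCounts(a)), as.matrix(umiCounts(c))))
})

test_that("emitted datasets round-trip through the readers unchanged", {
  x <- simulateDataset(tinyDesign(), seed = 12)
  d <- withr::local_tempdir()
  writeUmiMatrix(umiCounts(x), d)
  back <- readUmiMatrix(file.path(d, "matrix.mtx"), file.path(d, "genes.tsv"),
                        file.path(d, "barcodes.tsv"))
  expect_equal(as.matrix(back), as.matrix(umiCounts(x)))
  expect_identical(dimnames(back), dimnames(umiCounts(x)))
})

test_that("realized library sizes and stratum structure match the design", {
  des <- tinyDesign(cellsPerSegment = 200L)
  x <- simulateDataset(des, seed = 44)
  expect_equal(ncol(x), 200 * 3 * 3)
  cc <- groundTruth(x)$cell_counts
  expect_equal(sum(cc$n_cells), ncol(x))
  obs <- table(cellSamples(x), cellSegments(x))
  expect_true(all(obs == 200))
  # mean library size within 3 standard errors of the log-normal mean
  L <- Matrix::colSums(umiCounts(x))
  mu <- exp(des@libSizeMeanLog + des@libSizeSdLog^2 / 2)
  se <- sd(L) / sqrt(length(L))
  expect_lt(abs(mean(L) - mu), 3 * se + 1)  # +1 for the rounding floor
  # every planted gene exists in the emitted gene table
  tr <- groundTruth(x)
  expect_true(all(unlist(lapply(tr[c("marker", "segmental", "age")],
                                function(t) t$gene_id)) %in% rownames(x)))
})

test_that("MT weight rescaling hits the per-segment targets", {
  des <- tinyDesign(cellsPerSegment = 400L)
  x <- simulateDataset(des, seed = 50)
  fr <- cellMtFraction(x)
  for (sg in c("caput", "corpus", "cauda")) {
    expect_lt(abs(mean(fr[as.character(cellSegments(x)) == sg]) -
                    des@mtFractionTargets[[sg]]), 0.01)
  }
  expect_error(simulateDataset(tinyDesign(
    mtFractionTargets = c(caput = 0.999, corpus = 0.17, cauda = 0.14))),
    NA)  # feasible extreme is allowed; infeasibility is >= 1, checked below
  expect_error(simDesign(mtFractionTargets = c(caput = 1.0, corpus = 0.2,
                                               cauda = 0.2)), "\\(0, 1\\)")
})

test_that("detection-target calibration lands near the requested fraction", {
  des <- tinyDesign(cellsPerSegment = 300L, segmentalEffectSpec = data.frame(
    gene_id = NA, cluster = "principal", segment = "caput",
    effect = 3, detect_target = 0.4))
  x <- simulateDataset(des, seed = 77)
  tr <- groundTruth(x)$segmental
  sel <- cellClusters(x) == "principal" &
    as.character(cellSegments(x)) == "caput"
  det <- mean(umiCounts(x)[tr$gene_id, sel] > 0)
  expect_gt(det, 0.25)
  expect_lt(det, 0.55)
})

test_that("recovery scoring arithmetic", {
  truth <- list(segmental = data.frame(
    gene_id = sprintf("g%02d", 1:10), cluster = "c1", segment = "caput",
    effect = 3), age = NULL, marker = NULL)
  called <- data.frame(gene_id = c(sprintf("g%02d", 1:9), "x1"),
                       cluster = "c1", high_segment = "caput",
                       retained_specific = TRUE)
  r <- scoreRecovery(called, truth, "segmental",
                     geneUniverse = c(sprintf("g%02d", 1:10), "x1"))
  expect_equal(r$sensitivity, 0.9)
  expect_equal(r$fdp, 0.1)
  none <- called[0, ]
  r0 <- scoreRecovery(none, truth, "segmental")
  expect_equal(r0$sensitivity, 0)
  expect_equal(r0$fdp, 0)
  all10 <- data.frame(gene_id = sprintf("g%02d", 1:10), cluster = "c1",
                      high_segment = "caput", retained_specific = TRUE)
  r1 <- scoreRecovery(all10, truth, "segmental")
  expect_equal(r1$sensitivity, 1)
  expect_equal(r1$fdp, 0)
  expect_error(scoreRecovery(called, truth, "segmental",
                             geneUniverse = sprintf("g%02d", 1:10)),
               "universe")
})
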