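test_that("QC filters remove exactly the rows and columns the thresholds dictate", {
  x <- toyQcMatrix()

  # gene floor: UMI > 0 in >= 3 cells; Lcn5 sits exactly on the floor
  g <- filterGenesMinCells(x, 3)
  expect_identical(rownames(g), c("Aqp9", "Lcn5", "Hba-a1", "mt-Cytb"))
  expect_identical(rownames(filterGenesMinCells(x, 0)), rownames(x))

  # detected-gene range, inclusive bounds scaled to the toy (2 to 4):
  # detected after the gene filter are c1=4 c2=2 c3=3 c4=4 c5=3 c6=1
  gc <- filterCellsGeneRange(g, 2, 4)
  expect_identical(colnames(gc), paste0("c", 1:5))

  # globin removal drops Hba-a1 and nothing else, counts untouched
  gcg <- dropGlobinGenes(gc)
  expect_identical(rownames(gcg), c("Aqp9", "Lcn5", "mt-Cytb"))
  expect_equal(as.matrix(umiCounts(gcg)),
               as.matrix(umiCounts(gc))[c("Aqp9", "Lcn5", "mt-Cytb"), ])

  # the QC log reconstructs the accounting
  expect_equal(qcSummary(gcg)$removed, c(1, 1, 1))
})

test_that("strict boundary cases around the cell gene-range", {
  x <- toySegExperiment(nGenes = 20)
  det <- Matrix::colSums(umiCounts(x) > 0)
  lo <- min(det); hi <- max(det)
  kept <- filterCellsGeneRange(x, lo, hi)       # inclusive: identity
  expect_equal(ncol(kept), ncol(x))
  trimmed <- filterCellsGeneRange(x, lo + 1, hi)
  expect_equal(ncol(trimmed), sum(det >= lo + 1))
  expect_true(all(Matrix::colSums(umiCounts(trimmed) > 0) >= lo + 1))
})

test_that("dropCluster removes cells and warns on unknown labels", {
  x <- toySegExperiment()
  cellClusters(x) <- ifelse(seq_len(ncol(x)) <= 10, "erythrocyte",
                            cellClusters(x))
  y <- dropCluster(x, "erythrocyte")
  expect_equal(ncol(y), ncol(x) - 10)
  expect_false("erythrocyte" %in% cellClusters(y))
  expect_warning(z <- dropCluster(x, "no-such-cluster"), "not present")
  expect_equal(ncol(z), ncol(x))
})

test_that("log1pRPM matches its closed form and preserves zeros", {
  cnt <- matrix(c(1, 1000,
                  999, 0), nrow = 2, byrow = TRUE,
                dimnames = list(c("gA", "gB"), c("cellA", "cellB")))
  cells <- data.frame(barcode = c("cellA", "cellB"), sample_id = "S1",
                      segment = "caput", age = "P42")
  x <- computeLog1pRPM(SegExperiment(cnt, cells))
  v <- as.matrix(log1pRPM(x))
  # count 1 of 1000 total -> ln(1 + 1e6/1000) = ln(1001)
  expect_equal(v["gA", "cellA"], log(1001), tolerance = 1e-10)
  # count 1000 of 1000 -> ln(1 + 1e6)
  expect_equal(v["gA", "cellB"], log(1 + 1e6), tolerance = 1e-10)
  expect_equal(round(log(1001), 4), 6.9088)
  expect_equal(round(log(1 + 1e6), 4), 13.8155)
  # zero count -> zero value, exactly
  expect_identical(v["gB", "cellB"], 0)

  # zero-total cells are refused with guidance
  cnt0 <- cbind(cnt, cellC = c(0, 0))
  cells0 <- rbind(cells, data.frame(barcode = "cellC", sample_id = "S1",
                                    segment = "caput", age = "P42"))
  expect_error(computeLog1pRPM(SegExperiment(cnt0, cells0)),
               "cell filtering")
})

test_that("log1pRPM is strictly monotone per cell and gene-order invariant", {
  x <- computeLog1pRPM(toySegExperiment())
  v <- as.matrix(log1pRPM(x))
  cnt <- as.matrix(umiCounts(x))
  for (j in 1:5) {
    ord <- order(cnt[, j])
    expect_true(all(diff(v[ord, j])[diff(cnt[ord, j]) > 0] > 0))
  }
  perm <- sample(nrow(x))
  xp <- computeLog1pRPM(toySegExperiment()[perm, ])
  expect_equal(as.matrix(log1pRPM(xp)), v[perm, ])
})

test_that("independent QC filters commute", {
  x <- toySegExperiment(seed = 11)
  a <- dropGlobinGenes(filterGenesMinCells(x, 3))
  b <- filterGenesMinCells(dropGlobinGenes(x), 3)
  expect_identical(rownames(a), rownames(b))
  expect_equal(as.matrix(umiCounts(a)), as.matrix(umiCounts(b)))
})
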