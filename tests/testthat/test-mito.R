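test_that("per-cell MT fraction is the mitochondrial share of UMIs", {
  cnt <- matrix(c(10, 90,
                  90, 40,
                  50, 0), nrow = 3, byrow = TRUE,
                dimnames = list(c("mt-Nd1", "Actb", "mt-Cytb"),
                                c("cellA", "cellB")))
  cells <- data.frame(barcode = c("cellA", "cellB"), sample_id = "S1",
                      segment = c("caput", "corpus"), age = "P42")
  x <- SegExperiment(cnt, cells)
  fr <- cellMtFraction(x)
  expect_equal(unname(fr["cellA"]), 60 / 150)
  expect_equal(unname(fr["cellB"]), 90 / 130)
  # mt + non-mt fractions partition each cell exactly
  nonMt <- Matrix::colSums(umiCounts(x)[!mitoGenes(x), , drop = FALSE]) /
    Matrix::colSums(umiCounts(x))
  expect_equal(unname(fr + nonMt), c(1, 1))

  # all counts mitochondrial -> fraction 1
  y <- SegExperiment(cnt[c("mt-Nd1", "mt-Cytb"), ], cells)
  expect_equal(unname(cellMtFraction(y)), c(1, 1))

  # no mitochondrial genes -> zeros with a warning
  z <- SegExperiment(cnt["Actb", , drop = FALSE][, 2, drop = FALSE],
                     cells[2, ])
  expect_warning(fr0 <- cellMtFraction(z), "no mitochondrial")
  expect_equal(unname(fr0), 0)
})

test_that("aggregation groups correctly and recombines by weighted mean", {
  x <- toySegExperiment(seed = 15)
  fr <- cellMtFraction(x)
  agg <- aggregateMtFractions(x, "segment")
  expect_setequal(agg$segment, c("caput", "corpus", "cauda"))
  expect_equal(sum(agg$n_cells), ncol(x))
  for (sg in agg$segment) {
    sel <- as.character(cellSegments(x)) == sg
    expect_equal(agg$mean_mt_fraction[agg$segment == sg], mean(fr[sel]))
  }
  # splitting a group by sample and recombining by weighted mean agrees
  agg2 <- aggregateMtFractions(x, c("sample_id", "segment"))
  for (sg in agg$segment) {
    part <- agg2[agg2$segment == sg, ]
    expect_equal(sum(part$mean_mt_fraction * part$n_cells) / sum(part$n_cells),
                 agg$mean_mt_fraction[agg$segment == sg], tolerance = 1e-12)
  }
  # cell order does not matter
  xp <- x[, rev(seq_len(ncol(x)))]
  expect_equal(aggregateMtFractions(xp, "segment"), agg)
})

test_that("segment comparison ranks and reports pairwise differences", {
  agg <- data.frame(segment = c("caput", "corpus", "cauda"),
                    mean_mt_fraction = c(0.077, 0.170, 0.137))
  cmp <- compareSegmentsMt(agg)
  expect_equal(attr(cmp, "ordering")$all, c("corpus", "cauda", "caput"))
  expect_equal(cmp$difference[cmp$higher_segment == "corpus" &
                                cmp$lower_segment == "caput"], 0.093)
  expect_false(any(cmp$tied))

  tie <- data.frame(segment = c("caput", "corpus"),
                    mean_mt_fraction = c(0.1, 0.1))
  expect_true(all(compareSegmentsMt(tie)$tied))

  one <- data.frame(segment = "caput", mean_mt_fraction = 0.1)
  expect_error(compareSegmentsMt(one), "nothing to compare")
})

test_that("the optional max-MT cell filter is inclusive at the bound", {
  x <- toySegExperiment(seed = 8)
  fr <- cellMtFraction(x)
  cut <- stats::median(fr)
  y <- filterCellsMaxMt(x, cut)
  expect_equal(ncol(y), sum(fr <= cut))
  expect_true(all(cellMtFraction(y) <= cut))
  expect_equal(ncol(filterCellsMaxMt(x, 1)), ncol(x))
})
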