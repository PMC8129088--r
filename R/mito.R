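#' Per-cell mitochondrial transcript fraction
#'
#' Fraction of each cell's UMIs on mitochondrially encoded genes
#' (ids matching the configured prefix, default `"mt-"`,
#' case-insensitive). Computed on the current count matrix; the intended
#' stage is after cell/gene QC and before globin removal.
#'
#' @param x A [SegExperiment-class]; every cell must have total UMI > 0.
#' @return Named numeric vector of fractions in \[0, 1\], one per barcode.
#'   If no gene is flagged mitochondrial, all fractions are 0 with a
#'   warning.
#' @export
cellMtFraction <- function(x) {
  tot <- Matrix::colSums(umiCounts(x))
  if (any(tot == 0))
    stop(sum(tot == 0), " cell(s) have zero total UMI; filter cells first")
  mt <- mitoGenes(x)
  if (!any(mt)) {
    warning("no mitochondrial genes present; all fractions are 0")
    return(stats::setNames(rep(0, ncol(x)), colnames(x)))
  }
  mtSum <- Matrix::colSums(umiCounts(x)[mt, , drop = FALSE])
  stats::setNames(as.numeric(mtSum / tot), colnames(x))
}

#' Aggregate mitochondrial fractions
#'
#' Mean, median and cell count of per-cell MT fractions by any combination
#' of `sample_id`, `segment`, `cluster` and `age`. Empty groups are absent
#' from the output.
#'
#' @param x A [SegExperiment-class].
#' @param groupBy Character subset of
#'   `c("sample_id", "segment", "cluster", "age")`.
#' @param fractions Optional precomputed per-cell fractions (defaults to
#'   [cellMtFraction()] of `x`).
#' @return `data.frame` with the grouping columns plus `mean_mt_fraction`,
#'   `median_mt_fraction`, `n_cells`.
#' @export
#' @examples
#' sim <- simulateDataset(simDesign(nGenes = 60, cellsPerSegment = 60))
#' aggregateMtFractions(sim, "segment")
aggregateMtFractions <- function(x, groupBy = c("sample_id", "segment", "cluster"),
                                 fractions = cellMtFraction(x)) {
  ok <- c("sample_id", "segment", "cluster", "age")
  if (!all(groupBy %in% ok))
    stop("groupBy must be a subset of: ", paste(ok, collapse = ", "))
  cd <- as.data.frame(colData(x))[, groupBy, drop = FALSE]
  for (k in groupBy) cd[[k]] <- as.character(cd[[k]])
  key <- interaction(cd, drop = TRUE, sep = "\r")
  agg <- data.frame(do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE)),
                    stringsAsFactors = FALSE)
  colnames(agg) <- groupBy
  agg$mean_mt_fraction <- as.numeric(tapply(fractions, key, mean))
  agg$median_mt_fraction <- as.numeric(tapply(fractions, key, stats::median))
  agg$n_cells <- as.integer(tapply(fractions, key, length))
  agg[do.call(order, agg[groupBy]), , drop = FALSE] -> agg
  rownames(agg) <- NULL
  agg
}

#' Rank segments by mitochondrial fraction
#'
#' Descriptive comparison (no hypothesis test): per cluster (or overall),
#' orders the segments by mean MT fraction and reports all pairwise
#' differences. Exact ties are flagged.
#'
#' @param x A [SegExperiment-class], or a `data.frame` from
#'   [aggregateMtFractions()] containing `segment` and `mean_mt_fraction`
#'   (and optionally `cluster`).
#' @return `data.frame` with one row per (cluster,) segment pair:
#'   `higher_segment`, `lower_segment`, `difference`, `tied`; ordered by
#'   decreasing mean within cluster. The attribute `"ordering"` holds the
#'   segment ranking per cluster.
#' @export
compareSegmentsMt <- function(x) {
  agg <- if (methods::is(x, "SegExperiment")) {
    aggregateMtFractions(x, "segment")
  } else x
  split_by <- if ("cluster" %in% colnames(agg)) agg$cluster else
    rep("all", nrow(agg))
  pieces <- split(agg, split_by)
  ordering <- list()
  rows <- lapply(names(pieces), function(cl) {
    a <- pieces[[cl]]
    means <- tapply(a$mean_mt_fraction, a$segment, mean)
    if (length(means) < 2L) stop("nothing to compare: only one segment")
    means <- sort(means, decreasing = TRUE)
    ordering[[cl]] <<- names(means)
    pr <- utils::combn(seq_along(means), 2)
    data.frame(cluster = cl,
               higher_segment = names(means)[pr[1, ]],
               lower_segment = names(means)[pr[2, ]],
               difference = means[pr[1, ]] - means[pr[2, ]],
               tied = means[pr[1, ]] == means[pr[2, ]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ordering") <- ordering
  out
}

#' Optional maximum-MT cell filter
#'
#' Removes cells whose mitochondrial UMI fraction exceeds `maxFrac`. Not
#' part of the default QC chain: the analysis treats segment-graded MT
#' content as signal, so no MT-based cell exclusion is applied unless
#' explicitly requested.
#'
#' @param x A [SegExperiment-class].
#' @param maxFrac Fraction in \[0, 1\]; cells strictly above it are removed.
#' @return The filtered `SegExperiment`.
#' @export
filterCellsMaxMt <- function(x, maxFrac) {
  stopifnot(maxFrac >= 0, maxFrac <= 1)
  keep <- cellMtFraction(x) <= maxFrac
  .log_qc(x[, keep], "filter_cells_max_mt",
          removed = sum(!keep), kept = sum(keep))
}
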