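#' Call age-related differentially expressed genes (P42 vs P56)
#'
#' Per cluster x segment stratum, each gene's log1pRPM is compared between
#' cells of the two ages with a two-group Kruskal-Wallis rank test
#' (equivalent to a tie-corrected Wilcoxon), Bonferroni-adjusted over the
#' genes in the stratum. A gene is significant when, strictly:
#' the maximal detection percentage (UMI > 0) in either age group exceeds
#' `ageDetectThreshold` (default 0.5), the absolute log1pRPM difference
#' between the groups exceeds `ageDiffThreshold` (default 1), and the
#' adjusted p is below `ageAlpha` (default 0.01).
#'
#' The group difference is, by default, the difference of age-group means of
#' per-cell log1pRPM (`ageDiffMethod = "cell_mean"`), reported as P56 minus
#' P42; `"log1p_mean_rpm"` instead differences `log1p` of the age-group
#' mean RPM.
#'
#' Strata with only one age represented (or fewer than `minCellsPerGroup`
#' cells in a group) are skipped with a warning.
#'
#' @param x A normalized [SegExperiment-class] with cluster labels and both
#'   ages.
#' @param params A [SegParams-class].
#' @param clusters Clusters to analyze (default: all labels present).
#' @return `data.frame`, one row per gene x cluster x segment, with
#'   `p_adj`, `detect_prop_P42`, `detect_prop_P56`, `log1prpm_diff`
#'   (P56 - P42) and `significant`.
#' @export
callAgeDegs <- function(x, params = segParams(), clusters = NULL) {
  expr <- log1pRPM(x)
  cnt <- umiCounts(x)
  tot <- Matrix::colSums(cnt)
  rpm <- cnt %*% Matrix::Diagonal(x = 1e6 / tot)
  dimnames(rpm) <- dimnames(cnt)
  if (is.null(clusters)) clusters <- sort(unique(cellClusters(x)))
  genes <- rownames(x)
  nG <- length(genes)
  out <- list()
  for (cl in clusters) {
    for (sg in .SEGMENT_LEVELS) {
      sel <- cellClusters(x) == cl & as.character(cellSegments(x)) == sg
      if (!any(sel)) next
      age <- droplevels(cellAges(x)[sel])
      sizes <- table(factor(as.character(age), levels = .AGE_LEVELS))
      if (any(sizes < params@minCellsPerGroup)) {
        warning("cluster '", cl, "', segment '", sg,
                "': both ages need >= ", params@minCellsPerGroup,
                " cells; stratum skipped")
        next
      }
      g <- factor(as.character(cellAges(x)[sel]), levels = .AGE_LEVELS)
      kw <- .rowKruskal(as.matrix(expr[, sel, drop = FALSE]), g)
      padj <- bonferroniAdjust(kw$p, m = nG)
      j42 <- sel & as.character(cellAges(x)) == "P42"
      j56 <- sel & as.character(cellAges(x)) == "P56"
      d42 <- Matrix::rowSums(cnt[, j42, drop = FALSE] > 0) / sum(j42)
      d56 <- Matrix::rowSums(cnt[, j56, drop = FALSE] > 0) / sum(j56)
      if (params@ageDiffMethod == "cell_mean") {
        diff <- Matrix::rowMeans(expr[, j56, drop = FALSE]) -
          Matrix::rowMeans(expr[, j42, drop = FALSE])
      } else {
        diff <- log1p(Matrix::rowMeans(rpm[, j56, drop = FALSE])) -
          log1p(Matrix::rowMeans(rpm[, j42, drop = FALSE]))
      }
      out[[paste(cl, sg)]] <- data.frame(
        gene_id = genes, cluster = cl, segment = sg,
        p_adj = padj, detect_prop_P42 = d42, detect_prop_P56 = d56,
        log1prpm_diff = diff,
        significant = pmax(d42, d56) > params@ageDetectThreshold &
          abs(diff) > params@ageDiffThreshold & padj < params@ageAlpha,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) stop("no cluster x segment stratum had both ages")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
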