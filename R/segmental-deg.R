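#' Expressing proportion
#'
#' Fraction of cells in a subset with UMI count > 0 for a gene. The
#' segmental procedure compares this against its threshold strictly
#' ("larger than"), so exactly 25% fails the default 0.25 rule.
#'
#' @param counts Numeric vector of UMI counts for one gene over a non-empty
#'   cell subset.
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' expressingProportion(c(0, 0, 1, 3))  # 0.5
expressingProportion <- function(counts) {
  if (length(counts) == 0L) stop("empty cell subset")
  mean(counts > 0)
}

#' Segment fold change
#'
#' Identifies the segments with the highest and lowest mean RPM and returns
#' `ln((1 + RPM_high) / (1 + RPM_low))`, which equals the log1pRPM
#' difference of the two segment-level means. Ties resolve to the first
#' segment in the input order (caput, corpus, cauda by convention).
#'
#' @param meansRPM Named numeric vector of per-segment mean RPM (mean over
#'   cells of per-cell RPM), at least two segments.
#' @return List with `fold_change` (natural-log units, >= 0),
#'   `high_segment`, `low_segment`.
#' @export
#' @examples
#' segmentFoldChange(c(caput = 1000, corpus = 0, cauda = 10))  # ln(1001)
segmentFoldChange <- function(meansRPM) {
  if (length(meansRPM) < 2L) stop("need means for at least two segments")
  hi <- which.max(meansRPM)
  lo <- which.min(meansRPM)
  list(fold_change = log((1 + meansRPM[[hi]]) / (1 + meansRPM[[lo]])),
       high_segment = names(meansRPM)[hi],
       low_segment = names(meansRPM)[lo])
}

#' Call segmental differentially expressed genes
#'
#' The core multi-filter procedure, applied per cell cluster across the
#' caput / corpus / cauda segments:
#' \enumerate{
#'   \item Per sample, a Kruskal-Wallis test of each gene's log1pRPM across
#'     the segments, Bonferroni-adjusted over all genes entering the test;
#'     the combined p is the maximum of the per-sample adjusted p values and
#'     must be < `segAlpha`.
#'   \item Per sample, the expressing proportion (UMI > 0) in each segment;
#'     the sample-level minimum of the segment-highest proportion must be
#'     > `segPropThreshold`.
#'   \item Per sample, the fold change
#'     `ln((1 + RPM_high) / (1 + RPM_low))` between the extreme segments;
#'     the sample-level minimum must be > `segFcThreshold`.
#'   \item Specificity: only genes passing 1--3 in exactly one cluster are
#'     retained (`retained_specific`).
#' }
#' All comparisons are strict. Within a sample, segments contributing fewer
#' than `minCellsPerGroup` cells to the cluster are dropped; samples left
#' with fewer than two segments are skipped with a warning. Genes
#' untestable in a cluster count as non-passing there.
#'
#' @param x A normalized [SegExperiment-class] with cluster labels.
#' @param params A [SegParams-class].
#' @param clusters Clusters to analyze (default: all labels present).
#' @return `data.frame`, one row per gene x cluster, with per-sample
#'   adjusted p columns, `combined_p_adj`, pooled per-segment mean RPM
#'   (`mean_rpm_<segment>`), `fold_change`, `high_segment`, `low_segment`,
#'   `min_best_prop`, `min_fold_change`, filter verdicts (`pass_p`,
#'   `pass_prop`, `pass_fc`, `passes_all`) and `retained_specific`.
#' @export
callSegmentalDegs <- function(x, params = segParams(), clusters = NULL) {
  expr <- log1pRPM(x)
  cnt <- umiCounts(x)
  tot <- Matrix::colSums(cnt)
  rpm <- cnt %*% Matrix::Diagonal(x = 1e6 / tot)
  dimnames(rpm) <- dimnames(cnt)
  if (is.null(clusters)) clusters <- sort(unique(cellClusters(x)))
  samples <- sort(unique(cellSamples(x)))
  genes <- rownames(x)
  nG <- length(genes)
  segLv <- .SEGMENT_LEVELS

  res <- lapply(clusters, function(cl) {
    inCl <- cellClusters(x) == cl
    padj <- matrix(NA_real_, nG, length(samples),
                   dimnames = list(genes, samples))
    bestProp <- fcSample <- matrix(NA_real_, nG, length(samples),
                                   dimnames = list(genes, samples))
    used <- character()
    for (s in samples) {
      sel <- inCl & cellSamples(x) == s
      seg <- droplevels(cellSegments(x)[sel])
      keepSeg <- names(which(table(seg) >= params@minCellsPerGroup))
      if (length(keepSeg) < 2L) {
        warning("cluster '", cl, "', sample '", s,
                "': fewer than two segments with >= ",
                params@minCellsPerGroup, " cells; sample skipped")
        next
      }
      sel2 <- sel & as.character(cellSegments(x)) %in% keepSeg
      g <- droplevels(cellSegments(x)[sel2])
      used <- c(used, s)
      kw <- .rowKruskal(as.matrix(expr[, sel2, drop = FALSE]), g)
      padj[, s] <- bonferroniAdjust(kw$p, m = nG)
      segProp <- vapply(keepSeg, function(sg) {
        j <- sel2 & as.character(cellSegments(x)) == sg
        Matrix::rowSums(cnt[, j, drop = FALSE] > 0) / sum(j)
      }, numeric(nG))
      bestProp[, s] <- apply(segProp, 1, max)
      segMeanRpm <- vapply(keepSeg, function(sg) {
        j <- sel2 & as.character(cellSegments(x)) == sg
        Matrix::rowMeans(rpm[, j, drop = FALSE])
      }, numeric(nG))
      hi <- apply(segMeanRpm, 1, max)
      lo <- apply(segMeanRpm, 1, min)
      fcSample[, s] <- log((1 + hi) / (1 + lo))
    }
    if (length(used) == 0L) return(NULL)
    combined <- apply(padj[, used, drop = FALSE], 1, max)
    minBest <- apply(bestProp[, used, drop = FALSE], 1, min)
    minFc <- apply(fcSample[, used, drop = FALSE], 1, min)
    selAll <- inCl & cellSamples(x) %in% used
    pooled <- vapply(segLv, function(sg) {
      j <- selAll & as.character(cellSegments(x)) == sg
      if (!any(j)) return(rep(NA_real_, nG))
      Matrix::rowMeans(rpm[, j, drop = FALSE])
    }, numeric(nG))
    ok <- !apply(is.na(pooled), 2, all)
    hiIdx <- apply(pooled[, ok, drop = FALSE], 1, which.max)
    loIdx <- apply(pooled[, ok, drop = FALSE], 1, which.min)
    hiV <- pooled[, ok, drop = FALSE][cbind(seq_len(nG), hiIdx)]
    loV <- pooled[, ok, drop = FALSE][cbind(seq_len(nG), loIdx)]
    out <- data.frame(gene_id = genes, cluster = cl, stringsAsFactors = FALSE)
    for (s in samples) out[[paste0("p_adj_", s)]] <- padj[, s]
    out$combined_p_adj <- combined
    for (sg in segLv) out[[paste0("mean_rpm_", sg)]] <- pooled[, sg]
    out$fold_change <- log((1 + hiV) / (1 + loV))
    out$high_segment <- segLv[ok][hiIdx]
    out$low_segment <- segLv[ok][loIdx]
    out$min_best_prop <- minBest
    out$min_fold_change <- minFc
    out$n_samples_tested <- length(used)
    out$bonferroni_m <- nG
    out$pass_p <- combined < params@segAlpha
    out$pass_prop <- minBest > params@segPropThreshold
    out$pass_fc <- minFc > params@segFcThreshold
    out$passes_all <- out$pass_p & out$pass_prop & out$pass_fc
    out
  })
  res <- do.call(rbind, res)
  if (is.null(res)) stop("no cluster was testable for segmental DEGs")
  nPass <- tapply(res$passes_all, res$gene_id, sum)
  res$retained_specific <- res$passes_all &
    nPass[res$gene_id] == 1L
  rownames(res) <- NULL
  res
}
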