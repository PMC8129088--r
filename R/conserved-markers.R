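#' Conserved cluster markers across samples
#'
#' For each biological sample, the target cluster is compared to all other
#' clusters gene-by-gene with a one-vs-rest Wilcoxon rank-sum test on
#' log1pRPM, p values are Bonferroni-adjusted over the genes tested in that
#' sample's contrast, and the per-sample adjusted p values are combined by
#' taking their maximum. A gene is a conserved marker when the combined
#' adjusted p is below `markerAlpha` (default 0.05). Samples lacking the
#' target cluster (or having no other cells) are skipped with a warning.
#'
#' A pre-screen keeps only genes expressed (UMI > 0) in at least
#' `markerMinExprFrac` of the target-cluster cells of the sample; genes
#' screened out in a contributing sample cannot be conserved and carry
#' adjusted p = 1 there.
#'
#' @param x A normalized [SegExperiment-class] (run [computeLog1pRPM()]
#'   first) with cluster labels.
#' @param cluster Cluster label to profile, or `NULL` for all clusters.
#' @param params A [SegParams-class].
#' @return `data.frame` with one row per gene x cluster: per-sample adjusted
#'   p columns (`p_adj_<sample>`), `combined_p_adj`, `direction` (sign of
#'   cluster mean minus rest mean on log1pRPM), `n_samples_tested` and
#'   `significant`.
#' @export
conservedClusterMarkers <- function(x, cluster = NULL, params = segParams()) {
  if (is.null(cluster)) {
    cls <- sort(unique(cellClusters(x)))
    return(do.call(rbind, lapply(cls, conservedClusterMarkers, x = x,
                                 params = params)))
  }
  expr <- log1pRPM(x)
  cnt <- umiCounts(x)
  samples <- sort(unique(cellSamples(x)))
  inCl <- cellClusters(x) == cluster
  if (!any(inCl)) stop("cluster '", cluster, "' not present")
  genes <- rownames(x)
  padj <- matrix(NA_real_, length(genes), length(samples),
                 dimnames = list(genes, samples))
  mUsed <- stats::setNames(rep(NA_integer_, length(samples)), samples)
  used <- character()
  for (s in samples) {
    inS <- cellSamples(x) == s
    nTarget <- sum(inS & inCl)
    nRest <- sum(inS & !inCl)
    if (nTarget < 1L || nRest < 1L) {
      warning("sample '", s, "' lacks cluster '", cluster,
              "' or rest cells; skipped from the max-P combination")
      next
    }
    used <- c(used, s)
    sub <- as.matrix(expr[, inS, drop = FALSE])
    idx1 <- which(inCl[inS])
    frac <- Matrix::rowSums(cnt[, inS & inCl, drop = FALSE] > 0) / nTarget
    test <- frac >= params@markerMinExprFrac
    m <- sum(test)
    mUsed[s] <- m
    pa <- rep(1, length(genes))
    if (m > 0L) {
      res <- .rowWilcoxon(sub[test, , drop = FALSE], idx1)
      pa[test] <- bonferroniAdjust(res$p, m = m)
    }
    padj[, s] <- pa
  }
  if (length(used) == 0L) stop("no sample contains cluster '", cluster, "'")
  combined <- apply(padj[, used, drop = FALSE], 1, max)
  clMean <- Matrix::rowMeans(expr[, inCl, drop = FALSE])
  restMean <- Matrix::rowMeans(expr[, !inCl, drop = FALSE])
  out <- data.frame(gene_id = genes, cluster = cluster,
                    stringsAsFactors = FALSE)
  for (s in samples) out[[paste0("p_adj_", s)]] <- padj[, s]
  for (s in samples) out[[paste0("bonferroni_m_", s)]] <- mUsed[[s]]
  out$combined_p_adj <- combined
  out$direction <- sign(clMean - restMean)
  out$n_samples_tested <- length(used)
  out$significant <- combined < params@markerAlpha
  rownames(out) <- NULL
  out
}
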