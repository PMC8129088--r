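#' Gene QC: minimum expressing cells
#'
#' Retains genes with UMI > 0 in at least `minCells` cells (default 3,
#' matching standard first-level single-cell QC). Gene order is preserved.
#'
#' @param x A [SegExperiment-class].
#' @param minCells Non-negative integer threshold; `0` is the identity.
#' @return The filtered `SegExperiment`.
#' @export
filterGenesMinCells <- function(x, minCells = 3L) {
  stopifnot(minCells >= 0)
  keep <- Matrix::rowSums(umiCounts(x) > 0) >= minCells
  .log_qc(x[keep, ], "filter_genes_min_cells",
          removed = sum(!keep), kept = sum(keep))
}

#' Cell QC: detected-gene range
#'
#' Retains cells whose number of detected genes (UMI > 0, computed on the
#' current matrix) lies in the closed interval `[minGenes, maxGenes]`
#' (defaults 300 and 4000). Bounds are inclusive.
#'
#' @param x A [SegExperiment-class].
#' @param minGenes,maxGenes Inclusive bounds, `minGenes <= maxGenes`.
#' @return The filtered `SegExperiment`.
#' @export
filterCellsGeneRange <- function(x, minGenes = 300L, maxGenes = 4000L) {
  stopifnot(minGenes <= maxGenes)
  det <- Matrix::colSums(umiCounts(x) > 0)
  keep <- det >= minGenes & det <= maxGenes
  .log_qc(x[, keep], "filter_cells_gene_range",
          removed = sum(!keep), kept = sum(keep))
}

#' Remove globin genes
#'
#' Drops all genes flagged `is_globin` (erythrocyte contamination control);
#' counts of every other gene are untouched.
#'
#' @param x A [SegExperiment-class].
#' @return The filtered `SegExperiment`.
#' @export
dropGlobinGenes <- function(x) {
  keep <- !globinGenes(x)
  .log_qc(x[keep, ], "drop_globin_genes",
          removed = sum(!keep), kept = sum(keep))
}

#' Remove one cell cluster
#'
#' Drops every cell carrying `clusterLabel` (e.g. an erythrocyte cluster).
#' A missing label is a warning and a no-op, not an error.
#'
#' @param x A [SegExperiment-class].
#' @param clusterLabel Cluster label to remove.
#' @return The filtered `SegExperiment`.
#' @export
dropCluster <- function(x, clusterLabel) {
  hit <- cellClusters(x) == clusterLabel
  if (!any(hit)) {
    warning("cluster '", clusterLabel, "' not present; dataset unchanged")
    return(.log_qc(x, paste0("drop_cluster:", clusterLabel),
                   removed = 0L, kept = ncol(x)))
  }
  .log_qc(x[, !hit], paste0("drop_cluster:", clusterLabel),
          removed = sum(hit), kept = sum(!hit))
}

.log_qc <- function(x, step, removed, kept) {
  log <- metadata(x)$qc_log
  metadata(x)$qc_log <- rbind(log, data.frame(
    step = step, removed = removed, kept = kept, stringsAsFactors = FALSE))
  x
}

#' log1pRPM normalization
#'
#' Scales each cell's counts to reads per million of its current total UMI
#' and applies `log1p` (natural log), i.e.
#' `value = ln(1 + 1e6 * count / total_umi)`. Zeros map to zero exactly, so
#' sparsity is preserved. The result is stored as assay `"log1pRPM"`.
#'
#' @param x A [SegExperiment-class]; every cell must have total UMI > 0.
#' @return `x` with an added `log1pRPM` assay.
#' @name computeLog1pRPM
#' @export
#' @examples
#' sim <- simulateDataset(simDesign(nGenes = 50, cellsPerSegment = 30))
#' sim <- computeLog1pRPM(sim)
#' range(log1pRPM(sim))
computeLog1pRPM <- function(x) {
  tot <- Matrix::colSums(umiCounts(x))
  if (any(tot == 0))
    stop(sum(tot == 0), " cell(s) have zero total UMI; ",
         "apply cell filtering before normalization")
  rpm <- umiCounts(x) %*% Matrix::Diagonal(x = 1e6 / tot)
  v <- log1p(rpm)
  dimnames(v) <- dimnames(x)
  SummarizedExperiment::assay(x, "log1pRPM") <- v
  x
}

#' @describeIn computeLog1pRPM Accessor for the stored assay; errors if
#'   normalization has not been run.
#' @param x A [SegExperiment-class].
#' @export
setMethod("log1pRPM", "SegExperiment", function(x) {
  if (!"log1pRPM" %in% SummarizedExperiment::assayNames(x))
    stop("no log1pRPM assay; run computeLog1pRPM() first")
  assay(x, "log1pRPM")
})

#' Full QC + normalization chain
#'
#' Applies, in order: gene min-cells filter, cell detected-gene range
#' filter, globin removal, optional cluster exclusion, then log1pRPM
#' normalization (RPM denominator = total UMI after the filters applied so
#' far). Each step's removal counts are appended to `metadata(x)$qc_log`,
#' so the effect of ordering is recomputable.
#'
#' @param x A [SegExperiment-class].
#' @param params A [SegParams-class].
#' @param dropClusters Character vector of cluster labels to exclude (e.g.
#'   an erythrocyte cluster); default none.
#' @return A filtered, normalized `SegExperiment`.
#' @export
preprocess <- function(x, params = segParams(), dropClusters = character()) {
  x <- filterGenesMinCells(x, params@minCellsPerGene)
  x <- filterCellsGeneRange(x, params@minGenesPerCell, params@maxGenesPerCell)
  x <- dropGlobinGenes(x)
  for (cl in dropClusters) x <- dropCluster(x, cl)
  if (ncol(x) == 0L) {
    warning("no cells left after QC; returning empty dataset")
    return(x)
  }
  computeLog1pRPM(x)
}

#' QC summary table
#'
#' @param x A [SegExperiment-class] that has been through QC steps.
#' @return `data.frame` of per-step removal counts.
#' @export
qcSummary <- function(x) {
  log <- metadata(x)$qc_log
  if (is.null(log)) data.frame(step = character(), removed = integer(),
                               kept = integer()) else log
}
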