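#' @import methods
#' @importFrom SummarizedExperiment assay assays assay<- colData rowData
#' @importFrom S4Vectors metadata metadata<- DataFrame
NULL

#' Accessors for cell-level annotations of a SegExperiment
#'
#' Convenience generics returning the per-cell annotation columns a
#' segmental analysis relies on: sample of origin, epididymal segment
#' (caput / corpus / cauda), postnatal age (P42 / P56) and cluster label.
#'
#' @param x A [SegExperiment-class] object.
#' @param value Replacement value (character vector, one entry per cell).
#' @return A factor (segment, age) or character vector (sample, cluster)
#'   of length `ncol(x)`.
#' @examples
#' sim <- simulateDataset(simDesign(nGenes = 60, cellsPerSegment = 40))
#' table(cellSegments(sim), cellAges(sim))
#' @name cell-accessors
#' @aliases cellSegments cellAges cellSamples cellClusters cellClusters<-
NULL

#' @rdname cell-accessors
#' @export
setGeneric("cellSegments", function(x) standardGeneric("cellSegments"))

#' @rdname cell-accessors
#' @export
setGeneric("cellAges", function(x) standardGeneric("cellAges"))

#' @rdname cell-accessors
#' @export
setGeneric("cellSamples", function(x) standardGeneric("cellSamples"))

#' @rdname cell-accessors
#' @export
setGeneric("cellClusters", function(x) standardGeneric("cellClusters"))

#' @rdname cell-accessors
#' @export
setGeneric("cellClusters<-", function(x, value) standardGeneric("cellClusters<-"))

#' Gene-level flag accessors
#'
#' @param x A [SegExperiment-class] object.
#' @return A logical vector of length `nrow(x)`: `mitoGenes()` flags genes
#'   whose id starts with the configured mitochondrial prefix
#'   (case-insensitive, default `"mt-"`); `globinGenes()` flags genes in the
#'   configured globin list.
#' @examples
#' sim <- simulateDataset(simDesign(nGenes = 60, cellsPerSegment = 40))
#' sum(mitoGenes(sim))
#' @name gene-accessors
#' @aliases mitoGenes globinGenes
NULL

#' @rdname gene-accessors
#' @export
setGeneric("mitoGenes", function(x) standardGeneric("mitoGenes"))

#' @rdname gene-accessors
#' @export
setGeneric("globinGenes", function(x) standardGeneric("globinGenes"))

#' @rdname umiCounts
#' @export
setGeneric("umiCounts", function(x) standardGeneric("umiCounts"))

#' @rdname computeLog1pRPM
#' @export
setGeneric("log1pRPM", function(x) standardGeneric("log1pRPM"))

#' @rdname groundTruth
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
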