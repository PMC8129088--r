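#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SingleCellExperiment SingleCellExperiment
NULL

.SEGMENT_LEVELS <- c("caput", "corpus", "cauda")
.AGE_LEVELS <- c("P42", "P56")
.UNASSIGNED <- "unassigned"

#' Default globin gene list
#'
#' The five mouse globin genes routinely removed from epididymal single-cell
#' data to avoid erythrocyte contamination of downstream expression profiles.
#'
#' @return Character vector of gene symbols.
#' @export
#' @examples defaultGlobinGenes()
defaultGlobinGenes <- function() {
  c("Hba-a1", "Hba-a2", "Hba-ps4", "Hbb-bs", "Hbb-bt")
}

#' SegExperiment: segmented single-cell UMI experiment
#'
#' A thin extension of [SingleCellExperiment::SingleCellExperiment] that fixes
#' the contract a segmental differential-expression analysis needs: a
#' `counts` assay of non-negative integer UMIs (genes x cells) with unique
#' gene ids and cell barcodes, per-cell columns `sample_id`, `segment`
#' (caput / corpus / cauda), `age` (P42 / P56), `cluster`,
#' `n_genes_detected` and `total_umi`, and per-gene flags `is_mito` and
#' `is_globin`. Validity enforces all of this, so downstream callers can
#' assume it.
#'
#' @slot ... see [SingleCellExperiment::SingleCellExperiment].
#' @name SegExperiment-class
#' @aliases SegExperiment-class
#' @exportClass SegExperiment
setClass("SegExperiment", contains = "SingleCellExperiment")

.is_whole <- function(m) {
  x <- if (methods::is(m, "sparseMatrix")) m@x else as.vector(m)
  length(x) == 0L || (!anyNA(x) && all(x >= 0) && all(x == round(x)))
}

setValidity("SegExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (!.is_whole(cnt))
    msg <- c(msg, "counts must be non-negative integers")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "gene ids (rownames) and barcodes (colnames) are required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate cell barcodes")
  cd <- SummarizedExperiment::colData(object)
  need <- c("sample_id", "segment", "age", "cluster")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("missing colData columns: ", paste(miss, collapse = ", ")))
  if ("segment" %in% colnames(cd) &&
      !all(as.character(cd$segment) %in% .SEGMENT_LEVELS))
    msg <- c(msg, paste0("segment values must be one of: ",
                         paste(.SEGMENT_LEVELS, collapse = ", ")))
  if ("age" %in% colnames(cd) && !all(as.character(cd$age) %in% .AGE_LEVELS))
    msg <- c(msg, paste0("age values must be one of: ",
                         paste(.AGE_LEVELS, collapse = ", ")))
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("is_mito", "is_globin") %in% colnames(rd)))
    msg <- c(msg, "rowData must carry is_mito and is_globin")
  pre <- metadata(object)$mito_prefix
  if (!is.null(pre) && "is_mito" %in% colnames(rd)) {
    expect <- startsWith(tolower(rownames(object)), tolower(pre))
    if (!identical(as.logical(rd$is_mito), expect))
      msg <- c(msg, "is_mito inconsistent with the configured mito prefix")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SegExperiment
#'
#' Assembles a validated [SegExperiment-class] from a UMI count matrix and a
#' cell annotation table. Gene flags (`is_mito`, `is_globin`) are derived
#' from the mito prefix and globin list unless an explicit gene table is
#' supplied. Per-cell QC columns (`n_genes_detected`, `total_umi`) are
#' computed from the matrix.
#'
#' @param counts Matrix or sparse Matrix of non-negative integer UMI counts,
#'   genes x cells, with gene ids as rownames and barcodes as colnames.
#' @param cellData `data.frame` with columns `barcode`, `sample_id`,
#'   `segment` (caput/corpus/cauda), `age` (P42/P56) and optionally
#'   `cluster` (default `"unassigned"`). Must match the matrix barcodes
#'   bijectively.
#' @param geneData Optional `data.frame` with `gene_id`, `is_mito`,
#'   `is_globin`; derived from `mitoPrefix`/`globinGenes` when `NULL`.
#' @param mitoPrefix Case-insensitive gene-id prefix marking mitochondrially
#'   encoded transcripts (default `"mt-"`).
#' @param globinGenes Character vector of globin gene ids
#'   (default [defaultGlobinGenes()]).
#' @return A validated `SegExperiment`.
#' @export
#' @examples
#' cnt <- matrix(rpois(12, 2), 3, 4,
#'               dimnames = list(c("mt-Nd1", "Aqp9", "Hba-a1"),
#'                               paste0("BC", 1:4)))
#' cd <- data.frame(barcode = paste0("BC", 1:4), sample_id = "S1",
#'                  segment = "caput", age = "P42")
#' se <- SegExperiment(cnt, cd)
#' mitoGenes(se)
SegExperiment <- function(counts, cellData, geneData = NULL,
                          mitoPrefix = "mt-",
                          globinGenes = defaultGlobinGenes()) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene ids (rownames) and barcodes (colnames)")
  cellData <- as.data.frame(cellData)
  if (!"barcode" %in% colnames(cellData))
    stop("cellData must have a 'barcode' column")
  if (!setequal(cellData$barcode, colnames(counts)) ||
      anyDuplicated(cellData$barcode))
    stop("cellData barcodes must match the matrix barcodes bijectively")
  cellData <- cellData[match(colnames(counts), cellData$barcode), , drop = FALSE]
  if (!"cluster" %in% colnames(cellData)) cellData$cluster <- .UNASSIGNED
  cellData$cluster[is.na(cellData$cluster)] <- .UNASSIGNED
  if (is.null(geneData)) {
    geneData <- makeGeneTable(rownames(counts), mitoPrefix, globinGenes)
  } else {
    geneData <- as.data.frame(geneData)
    if (!identical(geneData$gene_id, rownames(counts)))
      geneData <- geneData[match(rownames(counts), geneData$gene_id), , drop = FALSE]
  }
  cd <- DataFrame(
    sample_id = as.character(cellData$sample_id),
    segment = factor(as.character(cellData$segment), levels = .SEGMENT_LEVELS),
    age = factor(as.character(cellData$age), levels = .AGE_LEVELS),
    cluster = as.character(cellData$cluster),
    n_genes_detected = Matrix::colSums(counts > 0),
    total_umi = Matrix::colSums(counts),
    row.names = colnames(counts))
  if (anyNA(cd$segment))
    stop("unknown segment token(s): ",
         paste(unique(setdiff(cellData$segment, .SEGMENT_LEVELS)), collapse = ", "))
  if (anyNA(cd$age))
    stop("unknown age token(s): ",
         paste(unique(setdiff(cellData$age, .AGE_LEVELS)), collapse = ", "))
  rd <- DataFrame(is_mito = geneData$is_mito, is_globin = geneData$is_globin,
                  row.names = rownames(counts))
  out <- methods::new("SegExperiment",
    SingleCellExperiment(assays = list(counts = counts),
                         colData = cd, rowData = rd))
  metadata(out)$mito_prefix <- mitoPrefix
  metadata(out)$globin_genes <- globinGenes
  methods::validObject(out)
  out
}

#' @rdname cell-accessors
setMethod("cellSegments", "SegExperiment", function(x) colData(x)$segment)
#' @rdname cell-accessors
setMethod("cellAges", "SegExperiment", function(x) colData(x)$age)
#' @rdname cell-accessors
setMethod("cellSamples", "SegExperiment", function(x) colData(x)$sample_id)
#' @rdname cell-accessors
setMethod("cellClusters", "SegExperiment", function(x) colData(x)$cluster)
#' @rdname cell-accessors
setMethod("cellClusters<-", "SegExperiment", function(x, value) {
  SummarizedExperiment::colData(x)$cluster <- as.character(value)
  x
})

#' @rdname gene-accessors
setMethod("mitoGenes", "SegExperiment", function(x) rowData(x)$is_mito)
#' @rdname gene-accessors
setMethod("globinGenes", "SegExperiment", function(x) rowData(x)$is_globin)

#' UMI count assay
#'
#' @param x A [SegExperiment-class].
#' @return The genes x cells count matrix.
#' @name umiCounts
#' @export
setMethod("umiCounts", "SegExperiment", function(x) assay(x, "counts"))

#' Ground truth of a simulated dataset
#'
#' Planted-effect records attached by [simulateDataset()]; `NULL` for real
#' data.
#'
#' @param x A [SegExperiment-class].
#' @return A list with elements `marker`, `segmental`, `age`, `cell_counts`
#'   and `seed`, or `NULL`.
#' @name groundTruth
#' @export
setMethod("groundTruth", "SegExperiment", function(x) metadata(x)$ground_truth)

setMethod("show", "SegExperiment", function(object) {
  methods::callNextMethod()
  seg <- table(cellSegments(object))
  cat("segments:", paste(names(seg), seg, sep = "=", collapse = " "), "\n")
  cat("samples:", paste(unique(cellSamples(object)), collapse = ", "), "\n")
  cat("mito genes:", sum(mitoGenes(object)),
      "| globin genes:", sum(globinGenes(object)), "\n")
})
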