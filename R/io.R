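#' @importFrom Matrix readMM writeMM colSums rowSums t
#' @importFrom utils read.delim write.table
NULL

.read_lines_tsv <- function(path, what) {
  x <- readLines(path)
  x <- x[nzchar(x)]
  # feature files from UMI pipelines may carry extra columns; first is the id
  ids <- vapply(strsplit(x, "\t", fixed = TRUE), `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate ", what, " in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ids
}

#' Read a UMI matrix from Matrix Market + id files
#'
#' Reads the conventional triplet layout of UMI-counting pipelines: a Matrix
#' Market coordinate file of integer counts plus one-id-per-line TSVs for
#' genes (rows) and cell barcodes (columns). Order is preserved from the
#' files; indices in the `.mtx` are 1-based per the Matrix Market standard.
#'
#' @param matrixPath Path to the `.mtx` coordinate file (integer entries).
#' @param genesPath Path to the gene-id TSV (first column used).
#' @param barcodesPath Path to the barcode TSV.
#' @param transpose If `TRUE` the `.mtx` is cells x genes and is transposed
#'   on read; the id files always refer to genes/barcodes respectively.
#' @return A sparse genes x cells `dgCMatrix` with gene ids as rownames and
#'   barcodes as colnames.
#' @export
#' @examples
#' d <- tempfile(); dir.create(d)
#' m <- Matrix::sparseMatrix(i = c(1, 3), j = c(1, 2), x = c(5, 2),
#'                           dims = c(3, 2))
#' Matrix::writeMM(m, file.path(d, "matrix.mtx"))
#' writeLines(c("g1", "g2", "g3"), file.path(d, "genes.tsv"))
#' writeLines(c("AAA", "CCC"), file.path(d, "barcodes.tsv"))
#' umi <- readUmiMatrix(file.path(d, "matrix.mtx"),
#'                      file.path(d, "genes.tsv"),
#'                      file.path(d, "barcodes.tsv"))
#' umi["g3", "CCC"]
readUmiMatrix <- function(matrixPath, genesPath, barcodesPath,
                          transpose = FALSE) {
  m <- Matrix::readMM(matrixPath)
  if (transpose) m <- Matrix::t(m)
  genes <- .read_lines_tsv(genesPath, "gene ids")
  barcodes <- .read_lines_tsv(barcodesPath, "barcodes")
  if (nrow(m) != length(genes))
    stop("matrix header declares ", nrow(m), " genes but ", genesPath,
         " has ", length(genes), " entries")
  if (ncol(m) != length(barcodes))
    stop("matrix header declares ", ncol(m), " cells but ", barcodesPath,
         " has ", length(barcodes), " entries")
  vals <- if (methods::is(m, "sparseMatrix")) m@x else as.vector(m)
  if (length(vals) && (any(vals < 0) || any(vals != round(vals))))
    stop("matrix entries must be non-negative integers")
  m <- methods::as(methods::as(m, "CsparseMatrix"), "dMatrix")
  dimnames(m) <- list(genes, barcodes)
  m
}

#' Write a UMI matrix as Matrix Market + id files
#'
#' Inverse of [readUmiMatrix()]: writes `matrix.mtx`, `genes.tsv` and
#' `barcodes.tsv` into `dir`.
#'
#' @param umi Genes x cells count matrix with dimnames.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeUmiMatrix <- function(umi, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(methods::as(umi, "CsparseMatrix"), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(umi), file.path(dir, "genes.tsv"))
  writeLines(colnames(umi), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read and validate a cell annotation table
#'
#' TSV with a header row naming at least `barcode`, `sample_id`, `segment`
#' and `age`; `cluster` is optional and defaults to `"unassigned"`. Segment
#' must be one of caput / corpus / cauda and age one of P42 / P56; offending
#' rows are named in the error.
#'
#' @param path TSV path.
#' @return A `data.frame` with validated enum columns.
#' @export
readCellTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "#")
  need <- c("barcode", "sample_id", "segment", "age")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("cell table is missing required column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(!tab$segment %in% .SEGMENT_LEVELS)
  if (length(bad))
    stop("unknown segment token(s) at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), ": ",
         paste(unique(tab$segment[bad]), collapse = ", "))
  bad <- which(!tab$age %in% .AGE_LEVELS)
  if (length(bad))
    stop("unknown age token(s) at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), ": ",
         paste(unique(tab$age[bad]), collapse = ", "))
  if (!"cluster" %in% colnames(tab)) tab$cluster <- .UNASSIGNED
  tab$cluster[is.na(tab$cluster) | tab$cluster == ""] <- .UNASSIGNED
  tab
}

#' Build a gene flag table
#'
#' @param geneIds Character vector of gene ids.
#' @param mitoPrefix Case-insensitive prefix marking mitochondrial genes.
#' @param globinGenes Globin gene ids (exact, case-sensitive match).
#' @return `data.frame` with `gene_id`, `is_mito`, `is_globin`.
#' @export
#' @examples
#' makeGeneTable(c("mt-Nd1", "Aqp9", "Hba-a1"))
makeGeneTable <- function(geneIds, mitoPrefix = "mt-",
                          globinGenes = defaultGlobinGenes()) {
  if (anyDuplicated(geneIds))
    stop("duplicate gene ids: ",
         paste(unique(geneIds[duplicated(geneIds)]), collapse = ", "))
  data.frame(gene_id = geneIds,
             is_mito = startsWith(tolower(geneIds), tolower(mitoPrefix)),
             is_globin = geneIds %in% globinGenes,
             stringsAsFactors = FALSE)
}

#' Validate a dataset for segmental analysis
#'
#' Reports barcode mismatches between matrix and cell table, duplicate ids,
#' and per-sample segment coverage. The dataset is `analyzable` only when
#' the ids are consistent and every sample contributes at least two
#' segments (a one-segment sample cannot enter a segmental contrast).
#'
#' @param umi Genes x cells count matrix with dimnames, or a
#'   [SegExperiment-class] (then `cells`/`genes` are taken from it).
#' @param cells Cell table as from [readCellTable()].
#' @param genes Optional gene table as from [makeGeneTable()].
#' @return A list of class `ValidationReport`: `issues` (character),
#'   `analyzable` (logical), `segment_coverage` (per-sample segment counts).
#' @export
validateDataset <- function(umi, cells = NULL, genes = NULL) {
  if (methods::is(umi, "SegExperiment")) {
    cells <- data.frame(barcode = colnames(umi),
                        sample_id = cellSamples(umi),
                        segment = as.character(cellSegments(umi)),
                        age = as.character(cellAges(umi)),
                        stringsAsFactors = FALSE)
    genes <- data.frame(gene_id = rownames(umi))
    umi <- umiCounts(umi)
  }
  issues <- character()
  if (anyDuplicated(rownames(umi)))
    issues <- c(issues, "duplicate gene ids in matrix")
  if (anyDuplicated(colnames(umi)))
    issues <- c(issues, "duplicate barcodes in matrix")
  if (anyDuplicated(cells$barcode))
    issues <- c(issues, "duplicate barcodes in cell table")
  onlyTab <- setdiff(cells$barcode, colnames(umi))
  onlyMat <- setdiff(colnames(umi), cells$barcode)
  if (length(onlyTab))
    issues <- c(issues, paste0(length(onlyTab),
      " barcode(s) in cell table absent from matrix (e.g. ", onlyTab[1], ")"))
  if (length(onlyMat))
    issues <- c(issues, paste0(length(onlyMat),
      " matrix barcode(s) absent from cell table (e.g. ", onlyMat[1], ")"))
  if (!is.null(genes) && !setequal(genes$gene_id, rownames(umi)))
    issues <- c(issues, "gene table does not match matrix gene ids")
  cov <- table(cells$sample_id, factor(cells$segment, levels = .SEGMENT_LEVELS))
  segsPerSample <- rowSums(cov > 0)
  under <- names(segsPerSample)[segsPerSample < 2]
  if (length(under))
    issues <- c(issues, paste0("sample(s) with <2 segments: ",
                               paste(under, collapse = ", ")))
  structure(list(issues = issues,
                 analyzable = length(issues) == 0L,
                 segment_coverage = cov),
            class = "ValidationReport")
}

#' @export
print.ValidationReport <- function(x, ...) {
  cat("ValidationReport: ",
      if (x$analyzable) "analyzable" else "NOT analyzable", "\n", sep = "")
  if (length(x$issues)) cat(paste0(" - ", x$issues, collapse = "\n"), "\n")
  invisible(x)
}

.write_tsv <- function(tab, path, digest = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(digest)) writeLines(paste0("# config_digest: ", digest), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
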