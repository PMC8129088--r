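#' Read a marker panel
#'
#' TSV with columns `gene_id` and `cell_type`. Each gene may map to exactly
#' one cell type; duplicate rows are errors. A provisional 26-gene
#' epididymal panel covering principal, myoid/fibroblast, clear/narrow,
#' macrophage/monocyte, basal, halo/T, endothelial and sperm populations
#' ships with the package and is user-replaceable.
#'
#' @param path TSV path; default is the shipped panel.
#' @return `data.frame` with `gene_id`, `cell_type`.
#' @export
#' @examples
#' head(readMarkerPanel())
readMarkerPanel <- function(path = system.file("extdata", "marker_panel.tsv",
                                               package = "scSegDEG")) {
  panel <- utils::read.delim(path, stringsAsFactors = FALSE,
                             comment.char = "#")
  need <- c("gene_id", "cell_type")
  if (!all(need %in% colnames(panel)))
    stop("marker panel must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(panel[need]))
    stop("duplicate (gene_id, cell_type) pairs in panel")
  multi <- unique(panel$gene_id[duplicated(panel$gene_id)])
  if (length(multi))
    stop("gene(s) mapped to more than one cell type: ",
         paste(multi, collapse = ", "))
  panel
}

#' Cluster mean expression
#'
#' Arithmetic mean of log1pRPM over the cells of each cluster, for a gene
#' subset.
#'
#' @param x A normalized [SegExperiment-class] with cluster labels.
#' @param genes Gene ids to average (default: all). Missing genes are an
#'   error naming them.
#' @return Matrix, clusters x genes, of mean log1pRPM.
#' @export
clusterMeanExpression <- function(x, genes = rownames(x)) {
  miss <- setdiff(genes, rownames(x))
  if (length(miss))
    stop("gene(s) absent from the matrix: ", paste(miss, collapse = ", "))
  expr <- log1pRPM(x)[genes, , drop = FALSE]
  cl <- cellClusters(x)
  cls <- sort(unique(cl))
  empty <- cls[!cls %in% cl]
  if (length(empty)) stop("empty cluster(s): ", paste(empty, collapse = ", "))
  out <- vapply(cls, function(k)
    Matrix::rowMeans(expr[, cl == k, drop = FALSE]), numeric(length(genes)))
  t(matrix(out, nrow = length(genes), dimnames = list(genes, cls)))
}

#' Annotate clusters from a marker panel
#'
#' For each cluster, the score of a cell type is the mean over that type's
#' marker genes of the cluster-mean log1pRPM; the assigned type is the
#' argmax. A cluster whose scores are all zero is labelled `"unknown"`.
#' Ties at the maximum are broken lexicographically and flagged.
#'
#' @param x A normalized [SegExperiment-class] with cluster labels.
#' @param panel Marker panel `data.frame` (`gene_id`, `cell_type`), e.g.
#'   from [readMarkerPanel()]. Must be non-empty and all genes present in
#'   `x`.
#' @return List with `assignments` (named character, cluster -> cell type),
#'   `scores` (clusters x cell types matrix, the audit table) and `tied`
#'   (named logical).
#' @export
annotateClusters <- function(x, panel = readMarkerPanel()) {
  if (nrow(panel) == 0L) stop("marker panel is empty")
  cm <- clusterMeanExpression(x, unique(panel$gene_id))
  types <- sort(unique(panel$cell_type))
  scores <- vapply(types, function(ty) {
    gs <- panel$gene_id[panel$cell_type == ty]
    rowMeans(cm[, gs, drop = FALSE])
  }, numeric(nrow(cm)))
  scores <- matrix(scores, nrow = nrow(cm),
                   dimnames = list(rownames(cm), types))
  assignments <- apply(scores, 1, function(s) {
    if (all(s == 0)) return("unknown")
    sort(names(s)[s == max(s)])[1]
  })
  tied <- apply(scores, 1, function(s) sum(s == max(s)) > 1L && any(s != 0))
  list(assignments = assignments, scores = scores, tied = tied)
}
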