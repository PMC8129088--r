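#' Run the analysis pipeline
#'
#' Chains the stages over one dataset with a single parameter object, writing
#' each stage's TSV (with the parameter digest in a comment header) plus a
#' run manifest. Stages are executed in dependency order regardless of the
#' order requested. A stage whose upstream output is neither requested nor
#' already present in `outDir` is an error naming the dependency.
#'
#' Stage outputs in `outDir`:
#' \describe{
#'   \item{simulate}{`matrix.mtx`, `genes.tsv`, `barcodes.tsv`, `cells.tsv`,
#'     `truth_*.tsv`, `design.json`}
#'   \item{preprocess}{`preprocessed/` (filtered matrix + tables),
#'     `qc_summary.tsv`}
#'   \item{annotate}{`cluster_annotation.tsv`}
#'   \item{markers}{`conserved_markers.tsv`}
#'   \item{segdeg}{`segmental_degs.tsv`}
#'   \item{agedeg}{`age_degs.tsv`}
#'   \item{mito}{`mt_fractions.tsv` (per-cell), `mt_aggregates.tsv`}
#' }
#' The mitochondrial statistics are computed on the QC-filtered matrix
#' before globin removal. Outputs are write-once: rerunning into a
#' non-empty `outDir` requires `overwrite = TRUE`.
#'
#' @param outDir Output directory (created).
#' @param stages Subset of
#'   `c("simulate", "preprocess", "annotate", "markers", "segdeg", "agedeg",
#'   "mito")`.
#' @param design [SimDesign-class] for the simulate stage.
#' @param params [SegParams-class] thresholds.
#' @param inputDir Directory holding `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`, `cells.tsv` when `simulate` is not requested.
#' @param panel Marker panel for the annotate stage.
#' @param dropClusters Cluster labels excluded during preprocessing.
#' @param overwrite Allow writing into a non-empty `outDir`.
#' @return `outDir`, invisibly; the manifest is `manifest.json`.
#' @export
runPipeline <- function(outDir,
                        stages = c("simulate", "preprocess", "annotate",
                                   "markers", "segdeg", "agedeg", "mito"),
                        design = simDesign(), params = segParams(),
                        inputDir = NULL, panel = readMarkerPanel(),
                        dropClusters = character(), overwrite = FALSE) {
  all_stages <- c("simulate", "preprocess", "annotate", "markers",
                  "segdeg", "agedeg", "mito")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!overwrite && file.exists(file.path(outDir, "manifest.json")))
    stop("outDir already holds a run; use overwrite = TRUE")
  t0 <- Sys.time()
  digest <- .paramsDigest(params)
  inputDigests <- list()

  need <- function(stage, dep, path) {
    if (!dep %in% stages && !file.exists(file.path(outDir, path)))
      stop("stage '", stage, "' requires the output of '", dep,
           "'; run it first or include it in `stages`")
  }

  x <- NULL
  if ("simulate" %in% stages) {
    x <- simulateDataset(design)
    writeUmiMatrix(umiCounts(x), outDir)
    .write_tsv(data.frame(barcode = colnames(x),
                          sample_id = cellSamples(x),
                          segment = as.character(cellSegments(x)),
                          age = as.character(cellAges(x)),
                          cluster = cellClusters(x)),
               file.path(outDir, "cells.tsv"), digest)
    tr <- groundTruth(x)
    for (nm in c("marker", "segmental", "age")) {
      if (!is.null(tr[[nm]]) && nrow(tr[[nm]]))
        .write_tsv(tr[[nm]], file.path(outDir, paste0("truth_", nm, ".tsv")),
                   digest)
    }
    jsonlite::write_json(list(seed = tr$seed, n_genes = nrow(x),
                              n_cells = ncol(x)),
                         file.path(outDir, "design.json"), auto_unbox = TRUE)
  } else {
    if (is.null(inputDir)) {
      need("preprocess", "simulate", "matrix.mtx")
      inputDir <- outDir
    }
    for (f in c("matrix.mtx", "genes.tsv", "barcodes.tsv", "cells.tsv"))
      inputDigests[[f]] <- unname(tools::md5sum(file.path(inputDir, f)))
    umi <- readUmiMatrix(file.path(inputDir, "matrix.mtx"),
                         file.path(inputDir, "genes.tsv"),
                         file.path(inputDir, "barcodes.tsv"))
    cells <- readCellTable(file.path(inputDir, "cells.tsv"))
    x <- SegExperiment(umi, cells, mitoPrefix = params@mitoPrefix,
                       globinGenes = params@globinGenes)
  }

  pre <- mito_input <- NULL
  downstream <- c("annotate", "markers", "segdeg", "agedeg")
  if (any(c("preprocess", "mito") %in% stages))
    need(if ("preprocess" %in% stages) "preprocess" else "mito",
         "simulate", "matrix.mtx")
  if ("preprocess" %in% stages || "mito" %in% stages) {
    qc <- filterGenesMinCells(x, params@minCellsPerGene)
    qc <- filterCellsGeneRange(qc, params@minGenesPerCell,
                               params@maxGenesPerCell)
    mito_input <- qc            # MT fractions: post cell/gene QC, pre globin
    if ("preprocess" %in% stages) {
      pre <- dropGlobinGenes(qc)
      for (cl in dropClusters) pre <- dropCluster(pre, cl)
      if (ncol(pre) == 0L) stop("no cells left after QC")
      pre <- computeLog1pRPM(pre)
      writeUmiMatrix(umiCounts(pre), file.path(outDir, "preprocessed"))
      .write_tsv(qcSummary(pre), file.path(outDir, "qc_summary.tsv"), digest)
    }
  }
  if (any(downstream %in% stages) && is.null(pre)) {
    for (st in intersect(downstream, stages))
      need(st, "preprocess", file.path("preprocessed", "matrix.mtx"))
    pdir <- file.path(outDir, "preprocessed")
    umi <- readUmiMatrix(file.path(pdir, "matrix.mtx"),
                         file.path(pdir, "genes.tsv"),
                         file.path(pdir, "barcodes.tsv"))
    cells <- readCellTable(file.path(outDir, "cells.tsv"))
    cells <- cells[cells$barcode %in% colnames(umi), , drop = FALSE]
    pre <- computeLog1pRPM(
      SegExperiment(umi, cells, mitoPrefix = params@mitoPrefix,
                    globinGenes = params@globinGenes))
  }
  if ("annotate" %in% stages) {
    ann <- annotateClusters(pre, panel)
    .write_tsv(data.frame(cluster = names(ann$assignments),
                          cell_type = ann$assignments,
                          tied = ann$tied),
               file.path(outDir, "cluster_annotation.tsv"), digest)
  }
  if ("markers" %in% stages)
    .write_tsv(conservedClusterMarkers(pre, NULL, params),
               file.path(outDir, "conserved_markers.tsv"), digest)
  if ("segdeg" %in% stages)
    .write_tsv(callSegmentalDegs(pre, params),
               file.path(outDir, "segmental_degs.tsv"), digest)
  if ("agedeg" %in% stages)
    .write_tsv(callAgeDegs(pre, params),
               file.path(outDir, "age_degs.tsv"), digest)
  if ("mito" %in% stages) {
    fr <- cellMtFraction(mito_input)
    .write_tsv(data.frame(barcode = names(fr), mt_fraction = fr),
               file.path(outDir, "mt_fractions.tsv"), digest)
    .write_tsv(aggregateMtFractions(mito_input, c("sample_id", "segment",
                                                  "cluster")),
               file.path(outDir, "mt_aggregates.tsv"), digest)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("scSegDEG")),
    stages = stages,
    config_digest = digest,
    config = jsonlite::parse_json(readChar(writeSegParams(params, tempfile()),
                                           1e6)),
    input_digests = inputDigests,
    seed = if ("simulate" %in% stages) design@rngSeed else params@rngSeed,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outDir)
}
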