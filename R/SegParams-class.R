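#' Analysis parameters
#'
#' Single source for every threshold of the pipeline. Defaults are the
#' published analysis settings: genes kept when expressed (UMI > 0) in at
#' least 3 cells; cells kept with 300--4000 detected genes (inclusive);
#' segmental calls require max-combined Bonferroni p < 0.05, best-segment
#' expressing proportion (sample-level minimum) > 0.25 and per-sample minimum
#' fold change > 2 natural-log units; conserved markers use combined p <
#' 0.05; age calls require detection > 0.5 in at least one age group,
#' |log1pRPM difference| > 1 and adjusted p < 0.01. All threshold
#' comparisons are strict, matching the "larger than" phrasing of the
#' procedure.
#'
#' @slot minCellsPerGene integer, gene QC floor (default 3).
#' @slot minGenesPerCell,maxGenesPerCell integer, inclusive cell QC bounds
#'   (defaults 300, 4000).
#' @slot segPropThreshold numeric, expressing-proportion threshold for
#'   segmental calls (default 0.25, strict).
#' @slot segFcThreshold numeric, fold-change threshold in natural-log units
#'   (default 2, i.e. about 7.4-fold linear; strict).
#' @slot segAlpha numeric, combined adjusted-p cutoff for segmental calls
#'   (default 0.05).
#' @slot markerAlpha numeric, combined adjusted-p cutoff for conserved
#'   markers (default 0.05).
#' @slot markerMinExprFrac numeric, minimum expressing fraction in the
#'   target cluster before a marker contrast is tested (default 0.10).
#' @slot ageDetectThreshold numeric, detection threshold for age calls
#'   (default 0.5, strict).
#' @slot ageDiffThreshold numeric, |log1pRPM difference| threshold (default 1,
#'   strict).
#' @slot ageAlpha numeric, adjusted-p cutoff for age calls (default 0.01).
#' @slot ageDiffMethod `"cell_mean"` (difference of age-group means of
#'   per-cell log1pRPM, the default) or `"log1p_mean_rpm"` (log1p of
#'   age-group mean RPM, the segmental-style alternative).
#' @slot minCellsPerGroup integer, smallest group size entering a rank test
#'   (default 3).
#' @slot mitoPrefix character, case-insensitive mitochondrial gene-id prefix
#'   (default `"mt-"`).
#' @slot globinGenes character, globin gene ids removed during QC.
#' @slot rngSeed integer seed recorded in run manifests.
#' @name SegParams-class
#' @exportClass SegParams
setClass("SegParams", representation(
  minCellsPerGene = "integer",
  minGenesPerCell = "integer",
  maxGenesPerCell = "integer",
  segPropThreshold = "numeric",
  segFcThreshold = "numeric",
  segAlpha = "numeric",
  markerAlpha = "numeric",
  markerMinExprFrac = "numeric",
  ageDetectThreshold = "numeric",
  ageDiffThreshold = "numeric",
  ageAlpha = "numeric",
  ageDiffMethod = "character",
  minCellsPerGroup = "integer",
  mitoPrefix = "character",
  globinGenes = "character",
  rngSeed = "integer"))

setValidity("SegParams", function(object) {
  msg <- character()
  frac <- function(v) length(v) == 1L && !is.na(v) && v >= 0 && v <= 1
  if (object@minCellsPerGene < 0L) msg <- c(msg, "minCellsPerGene must be >= 0")
  if (object@minGenesPerCell > object@maxGenesPerCell)
    msg <- c(msg, "minGenesPerCell must be <= maxGenesPerCell")
  for (s in c("segPropThreshold", "segAlpha", "markerAlpha",
              "markerMinExprFrac", "ageDetectThreshold", "ageAlpha")) {
    if (!frac(methods::slot(object, s))) msg <- c(msg, paste(s, "must be in [0, 1]"))
  }
  if (object@segFcThreshold < 0) msg <- c(msg, "segFcThreshold must be >= 0")
  if (object@ageDiffThreshold < 0) msg <- c(msg, "ageDiffThreshold must be >= 0")
  if (!object@ageDiffMethod %in% c("cell_mean", "log1p_mean_rpm"))
    msg <- c(msg, "ageDiffMethod must be 'cell_mean' or 'log1p_mean_rpm'")
  if (object@minCellsPerGroup < 1L) msg <- c(msg, "minCellsPerGroup must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn SegParams-class Constructor; any slot can be overridden by
#'   name.
#' @param ... named slot overrides.
#' @return A validated `SegParams` object.
#' @export
#' @examples
#' segParams()
#' segParams(segAlpha = 0.01, mitoPrefix = "MT-")
segParams <- function(...) {
  dots <- list(...)
  defaults <- list(
    minCellsPerGene = 3L, minGenesPerCell = 300L, maxGenesPerCell = 4000L,
    segPropThreshold = 0.25, segFcThreshold = 2, segAlpha = 0.05,
    markerAlpha = 0.05, markerMinExprFrac = 0.10,
    ageDetectThreshold = 0.5, ageDiffThreshold = 1, ageAlpha = 0.01,
    ageDiffMethod = "cell_mean", minCellsPerGroup = 3L,
    mitoPrefix = "mt-", globinGenes = defaultGlobinGenes(), rngSeed = 1L)
  bad <- setdiff(names(dots), names(defaults))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  defaults[names(dots)] <- dots
  ints <- c("minCellsPerGene", "minGenesPerCell", "maxGenesPerCell",
            "minCellsPerGroup", "rngSeed")
  for (s in ints) defaults[[s]] <- as.integer(defaults[[s]])
  do.call(methods::new, c(list(Class = "SegParams"), defaults))
}

setMethod("show", "SegParams", function(object) {
  cat("SegParams\n")
  for (s in methods::slotNames(object)) {
    v <- methods::slot(object, s)
    cat(sprintf("  %-20s %s\n", s, paste(v, collapse = ", ")))
  }
})

#' Read / write analysis parameters as flat JSON
#'
#' @param path File path of a flat JSON object keyed by `SegParams` slot
#'   names.
#' @param params A `SegParams` object.
#' @return `readSegParams` returns a `SegParams`; `writeSegParams` returns
#'   `path` invisibly.
#' @export
readSegParams <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(segParams, vals)
}

#' @rdname readSegParams
#' @export
writeSegParams <- function(params, path) {
  vals <- lapply(methods::slotNames(params), function(s) methods::slot(params, s))
  names(vals) <- methods::slotNames(params)
  jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.paramsDigest <- function(params) {
  vals <- lapply(methods::slotNames(params), function(s) methods::slot(params, s))
  names(vals) <- methods::slotNames(params)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(vals, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}
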