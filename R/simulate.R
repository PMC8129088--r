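.MT_GENES <- c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Atp8", "mt-Atp6",
               "mt-Co3", "mt-Nd3", "mt-Nd4l", "mt-Nd4", "mt-Nd5", "mt-Nd6",
               "mt-Cytb")

.DEFAULT_CLUSTER_PROPS <- c(
  principal = 0.60, myoid_fibroblast = 0.09, clear_narrow = 0.08,
  macrophage_monocyte = 0.06, basal = 0.07, halo_T = 0.05,
  endothelial = 0.03, sperm = 0.02)

#' Simulation design
#'
#' Parameters of the synthetic multi-sample UMI generator. The default
#' design mirrors the shape of the motivating study at desk scale: one P42
#' sample plus two P56 biological replicates, each dissected into caput,
#' corpus and cauda; eight cell clusters with roughly 60% principal cells;
#' segment-graded expected mitochondrial UMI fractions of 7.7% (caput),
#' 17.0% (corpus) and 13.7% (cauda); negative-binomial counts with a
#' gene-shared dispersion over log-normal baseline gene weights and
#' log-normal library sizes.
#'
#' @slot sampleIds,sampleAges Character vectors, one entry per sample.
#' @slot segments Segments dissected per sample.
#' @slot clusterProportions Named numeric summing to 1.
#' @slot cellsPerSegment Cells per (sample, segment); split across clusters
#'   by `clusterProportions` (every cluster gets at least one cell).
#' @slot nGenes Total genes, including 13 mitochondrial and 5 globin genes.
#' @slot baselineSdLog Log-normal sd of baseline gene weights.
#' @slot dispersion Negative-binomial size parameter (shared across genes).
#' @slot clusterMarkerSpec `data.frame(cluster, n_genes, effect)` of planted
#'   cluster markers (ln-scale multiplicative effects); an optional
#'   `detect_target` column calibrates marker baselines like the other
#'   effect specs.
#' @slot segmentalEffectSpec `data.frame(gene_id, cluster, segment, effect,
#'   detect_target)`; `gene_id = NA` auto-assigns unused filler genes;
#'   `detect_target` (optional, may be `NA`) calibrates the gene's baseline
#'   so its expected detection fraction in the boosted stratum is near the
#'   target.
#' @slot ageEffectSpec `data.frame(gene_id, cluster, segment, age, effect,
#'   detect_target)`; the effect multiplies expression in the stated age.
#' @slot mtFractionTargets Named numeric in (0, 1) per segment.
#' @slot libSizeMeanLog,libSizeSdLog Log-normal library-size parameters.
#' @slot rngSeed Integer seed; identical seeds give identical datasets.
#' @name SimDesign-class
#' @exportClass SimDesign
setClass("SimDesign", representation(
  sampleIds = "character", sampleAges = "character", segments = "character",
  clusterProportions = "numeric", cellsPerSegment = "integer",
  nGenes = "integer", baselineSdLog = "numeric", dispersion = "numeric",
  clusterMarkerSpec = "data.frame", segmentalEffectSpec = "data.frame",
  ageEffectSpec = "data.frame", mtFractionTargets = "numeric",
  libSizeMeanLog = "numeric", libSizeSdLog = "numeric", rngSeed = "integer"))

setValidity("SimDesign", function(object) {
  msg <- character()
  if (length(object@sampleIds) != length(object@sampleAges))
    msg <- c(msg, "sampleIds and sampleAges must align")
  if (!all(object@sampleAges %in% .AGE_LEVELS))
    msg <- c(msg, "sampleAges must be P42/P56")
  if (!all(object@segments %in% .SEGMENT_LEVELS))
    msg <- c(msg, "segments must be caput/corpus/cauda")
  if (abs(sum(object@clusterProportions) - 1) > 1e-6)
    msg <- c(msg, "clusterProportions must sum to 1")
  if (object@cellsPerSegment < length(object@clusterProportions))
    msg <- c(msg, "cellsPerSegment must cover every cluster")
  if (object@nGenes < length(.MT_GENES) + length(defaultGlobinGenes()) + 1L)
    msg <- c(msg, "nGenes too small for the fixed mito/globin genes")
  tg <- object@mtFractionTargets
  if (!all(names(tg) %in% .SEGMENT_LEVELS) || any(tg <= 0) || any(tg >= 1))
    msg <- c(msg, "mtFractionTargets must be named by segment, in (0, 1)")
  if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
  for (spec in list(object@clusterMarkerSpec)) {
    if (nrow(spec) && !all(c("cluster", "n_genes", "effect") %in% colnames(spec)))
      msg <- c(msg, "clusterMarkerSpec needs cluster, n_genes, effect")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SimDesign-class Constructor with study-shaped defaults; any
#'   slot can be overridden by name.
#' @param ... named slot overrides.
#' @return A validated `SimDesign`.
#' @export
#' @examples
#' simDesign(cellsPerSegment = 120, nGenes = 100)
simDesign <- function(...) {
  dots <- list(...)
  empty_seg <- data.frame(gene_id = character(), cluster = character(),
                          segment = character(), effect = numeric(),
                          detect_target = numeric(), stringsAsFactors = FALSE)
  empty_age <- data.frame(gene_id = character(), cluster = character(),
                          segment = character(), age = character(),
                          effect = numeric(), detect_target = numeric(),
                          stringsAsFactors = FALSE)
  defaults <- list(
    sampleIds = c("P42_1", "P56_1", "P56_2"),
    sampleAges = c("P42", "P56", "P56"),
    segments = .SEGMENT_LEVELS,
    clusterProportions = .DEFAULT_CLUSTER_PROPS,
    cellsPerSegment = 300L,
    nGenes = 500L,
    baselineSdLog = 1.5,
    dispersion = 2,
    clusterMarkerSpec = data.frame(cluster = character(),
                                   n_genes = integer(), effect = numeric(),
                                   stringsAsFactors = FALSE),
    segmentalEffectSpec = empty_seg,
    ageEffectSpec = empty_age,
    mtFractionTargets = c(caput = 0.077, corpus = 0.170, cauda = 0.137),
    libSizeMeanLog = log(3000), libSizeSdLog = 0.35,
    rngSeed = 1L)
  bad <- setdiff(names(dots), names(defaults))
  if (length(bad)) stop("unknown design field(s): ", paste(bad, collapse = ", "))
  defaults[names(dots)] <- dots
  defaults$cellsPerSegment <- as.integer(defaults$cellsPerSegment)
  defaults$nGenes <- as.integer(defaults$nGenes)
  defaults$rngSeed <- as.integer(defaults$rngSeed)
  for (nm in c("segmentalEffectSpec", "ageEffectSpec")) {
    sp <- defaults[[nm]]
    if (nrow(sp) && !"detect_target" %in% colnames(sp)) sp$detect_target <- NA_real_
    if (nrow(sp) && !"gene_id" %in% colnames(sp)) sp$gene_id <- NA_character_
    defaults[[nm]] <- sp
  }
  do.call(methods::new, c(list(Class = "SimDesign"), defaults))
}

setMethod("show", "SimDesign", function(object) {
  cat("SimDesign:", length(object@sampleIds), "sample(s) x",
      length(object@segments), "segment(s),",
      object@cellsPerSegment, "cells/segment,",
      object@nGenes, "genes\n")
  cat("  planted: ", nrow(object@clusterMarkerSpec), " marker spec(s), ",
      nrow(object@segmentalEffectSpec), " segmental, ",
      nrow(object@ageEffectSpec), " age effect(s)\n", sep = "")
})

# Split cellsPerSegment across clusters: floor + largest remainders, min 1.
.cluster_counts <- function(props, total) {
  raw <- props * total
  n <- pmax(1L, floor(raw))
  rem <- total - sum(n)
  if (rem > 0) {
    ord <- order(raw - floor(raw), decreasing = TRUE)
    idx <- rep(ord, length.out = rem)
    for (i in idx) n[i] <- n[i] + 1L
  } else if (rem < 0) {
    ord <- order(n, decreasing = TRUE)
    i <- 1L
    while (rem < 0) {
      if (n[ord[i]] > 1L) { n[ord[i]] <- n[ord[i]] - 1L; rem <- rem + 1L }
      i <- i %% length(ord) + 1L
    }
  }
  stats::setNames(as.integer(n), names(props))
}

# NB mean giving detection d at size k: solve 1 - (k/(k+mu))^k = d.
.mu_for_detection <- function(d, k) k * ((1 - d)^(-1 / k) - 1)

#' Simulate a multi-sample segmented UMI dataset
#'
#' Draws negative-binomial UMI counts per cell with expected value
#' `library_size * p_gc`, where `p_gc` is the cell's expected expression
#' proportion: log-normal baseline gene weights times the exponential of
#' every planted effect applying to the cell's (cluster, segment, age)
#' stratum, with the mitochondrial genes' total weight rescaled so each
#' segment's expected MT fraction equals its target. Deterministic given
#' the seed.
#'
#' @param design A [SimDesign-class].
#' @param seed Overrides `design@rngSeed` when given.
#' @return A [SegExperiment-class] whose `metadata` carries `ground_truth`
#'   (planted marker / segmental / age effect tables, realized per-stratum
#'   cell counts, and the seed; see [groundTruth()]).
#' @export
#' @examples
#' sim <- simulateDataset(simDesign(nGenes = 80, cellsPerSegment = 60))
#' sim
simulateDataset <- function(design, seed = design@rngSeed) {
  methods::validObject(design)
  set.seed(seed)
  nG <- design@nGenes
  globin <- defaultGlobinGenes()
  nFill <- nG - length(.MT_GENES) - length(globin)
  geneIds <- c(.MT_GENES, globin,
               sprintf("gene%05d", seq_len(nFill)))
  w0 <- stats::rlnorm(nG, meanlog = 0, sdlog = design@baselineSdLog)
  names(w0) <- geneIds
  isMt <- startsWith(tolower(geneIds), "mt-")
  clusters <- names(design@clusterProportions)

  # resolve auto-assigned planted genes and detection calibration
  usedGenes <- character()
  pickFiller <- function(n) {
    avail <- setdiff(geneIds[!isMt & !geneIds %in% globin], usedGenes)
    if (length(avail) < n) stop("not enough filler genes for planted effects")
    g <- avail[seq_len(n)]
    usedGenes <<- c(usedGenes, g)
    g
  }
  markerTruth <- NULL
  mspec <- design@clusterMarkerSpec
  if (nrow(mspec)) {
    if (!"detect_target" %in% colnames(mspec)) mspec$detect_target <- NA_real_
    markerTruth <- do.call(rbind, lapply(seq_len(nrow(mspec)), function(i) {
      data.frame(gene_id = pickFiller(mspec$n_genes[i]),
                 cluster = mspec$cluster[i], effect = mspec$effect[i],
                 detect_target = mspec$detect_target[i],
                 stringsAsFactors = FALSE)
    }))
  }
  resolveSpec <- function(sp) {
    if (!nrow(sp)) return(sp)
    na <- is.na(sp$gene_id)
    if (any(na)) sp$gene_id[na] <- pickFiller(sum(na))
    usedGenes <<- union(usedGenes, sp$gene_id)
    sp
  }
  segTruth <- resolveSpec(design@segmentalEffectSpec)
  ageTruth <- resolveSpec(design@ageEffectSpec)

  # detection-target calibration: set baseline weight so the boosted
  # stratum's expected NB mean yields the requested detection fraction
  # (approximate: uses the mean library size and unit total weight scale)
  Lbar <- exp(design@libSizeMeanLog + design@libSizeSdLog^2 / 2)
  Wref <- sum(w0)
  calibrate <- function(sp) {
    if (!nrow(sp)) return()
    for (i in seq_len(nrow(sp))) {
      d <- sp$detect_target[i]
      if (is.na(d)) next
      mu <- .mu_for_detection(d, design@dispersion)
      p <- mu / Lbar
      w0[sp$gene_id[i]] <<- p * Wref / (exp(sp$effect[i]) * (1 - p))
    }
  }
  calibrate(segTruth)
  calibrate(ageTruth)
  if (!is.null(markerTruth)) calibrate(markerTruth)

  nSeg <- length(design@segments)
  counts <- vector("list", length(design@sampleIds) * nSeg)
  cellRows <- vector("list", length(counts))
  cellCounts <- NULL
  blk <- 0L
  for (si in seq_along(design@sampleIds)) {
    s <- design@sampleIds[si]
    age <- design@sampleAges[si]
    for (sg in design@segments) {
      blk <- blk + 1L
      nPerCl <- .cluster_counts(design@clusterProportions,
                                design@cellsPerSegment)
      cellCounts <- rbind(cellCounts, data.frame(
        sample_id = s, segment = sg, cluster = names(nPerCl),
        n_cells = as.integer(nPerCl), stringsAsFactors = FALSE))
      blocks <- lapply(clusters, function(cl) {
        n <- nPerCl[[cl]]
        w <- w0
        if (!is.null(markerTruth)) {
          hit <- markerTruth$cluster == cl
          w[markerTruth$gene_id[hit]] <-
            w[markerTruth$gene_id[hit]] * exp(markerTruth$effect[hit])
        }
        if (nrow(segTruth)) {
          hit <- segTruth$cluster == cl & segTruth$segment == sg
          w[segTruth$gene_id[hit]] <-
            w[segTruth$gene_id[hit]] * exp(segTruth$effect[hit])
        }
        if (nrow(ageTruth)) {
          hit <- ageTruth$cluster == cl & ageTruth$segment == sg &
            ageTruth$age == age
          w[ageTruth$gene_id[hit]] <-
            w[ageTruth$gene_id[hit]] * exp(ageTruth$effect[hit])
        }
        tg <- design@mtFractionTargets[[sg]]
        Wmt <- sum(w[isMt])
        Wother <- sum(w[!isMt])
        if (Wmt <= 0 || tg >= 1)
          stop("infeasible MT target for segment ", sg)
        w[isMt] <- w[isMt] * tg * Wother / ((1 - tg) * Wmt)
        p <- w / sum(w)
        L <- pmax(100, round(stats::rlnorm(n, design@libSizeMeanLog,
                                           design@libSizeSdLog)))
        mu <- outer(p, L)
        matrix(stats::rnbinom(length(mu), mu = mu, size = design@dispersion),
               nrow = nG)
      })
      m <- do.call(cbind, blocks)
      bc <- sprintf("%s_%s_%04d", s, sg, seq_len(ncol(m)))
      colnames(m) <- bc
      rownames(m) <- geneIds
      counts[[blk]] <- m
      cellRows[[blk]] <- data.frame(
        barcode = bc, sample_id = s, segment = sg, age = age,
        cluster = rep(names(nPerCl), nPerCl), stringsAsFactors = FALSE)
    }
  }
  cnt <- methods::as(do.call(cbind, counts), "CsparseMatrix")
  cells <- do.call(rbind, cellRows)
  out <- SegExperiment(cnt, cells)
  metadata(out)$ground_truth <- list(
    marker = markerTruth, segmental = segTruth, age = ageTruth,
    cell_counts = cellCounts, seed = seed)
  metadata(out)$sim_design <- design
  out
}

#' Score recovery of planted effects
#'
#' Compares a DEG / marker call table with the generator's ground truth and
#' reports sensitivity (planted effects detected) and the false-discovery
#' proportion among calls (calls not planted).
#'
#' @param called The output of [callSegmentalDegs()], [callAgeDegs()] or
#'   [conservedClusterMarkers()], matching `type`.
#' @param truth A ground-truth list ([groundTruth()]) or the simulated
#'   [SegExperiment-class] itself.
#' @param type `"segmental"`, `"age"` or `"marker"`.
#' @param geneUniverse Gene ids of the analyzed matrix; every called gene
#'   must belong to it (defaults to the truth object's universe when a
#'   `SegExperiment` is given).
#' @return List with `sensitivity`, `fdp`, `n_called`, `n_planted` and
#'   `detected` (logical per planted effect).
#' @export
scoreRecovery <- function(called, truth,
                          type = c("segmental", "age", "marker"),
                          geneUniverse = NULL) {
  type <- match.arg(type)
  if (methods::is(truth, "SegExperiment")) {
    if (is.null(geneUniverse)) geneUniverse <- rownames(truth)
    truth <- groundTruth(truth)
  }
  if (is.null(truth)) stop("no ground truth available")
  if (!is.null(geneUniverse) && !all(called$gene_id %in% geneUniverse))
    stop("called table contains genes outside the ground-truth universe")
  planted <- switch(type, segmental = truth$segmental, age = truth$age,
                    marker = truth$marker)
  if (is.null(planted))
    planted <- data.frame(gene_id = character(), stringsAsFactors = FALSE)
  calls <- switch(type,
    segmental = called[called$retained_specific,
                       c("gene_id", "cluster", "high_segment")],
    age = called[called$significant, c("gene_id", "cluster", "segment")],
    marker = called[called$significant & called$direction > 0,
                    c("gene_id", "cluster")])
  detected <- if (nrow(planted) == 0L) logical(0) else
    vapply(seq_len(nrow(planted)), function(i) {
      hit <- calls$gene_id == planted$gene_id[i] &
        calls$cluster == planted$cluster[i]
      if (type == "segmental" && planted$effect[i] > 0)
        hit <- hit & calls$high_segment == planted$segment[i]
      if (type == "age")
        hit <- hit & calls$segment == planted$segment[i]
      any(hit)
    }, logical(1))
  # a call on any planted gene is not a false discovery: effects of one
  # type (e.g. a segmental boost) legitimately surface in other call types
  # (e.g. as a cluster marker)
  plantedAny <- unique(c(truth$segmental$gene_id, truth$age$gene_id,
                         truth$marker$gene_id))
  falseCalls <- !calls$gene_id %in% plantedAny
  list(sensitivity = if (nrow(planted)) mean(detected) else NA_real_,
       fdp = if (nrow(calls)) mean(falseCalls) else 0,
       n_called = nrow(calls), n_planted = nrow(planted),
       detected = detected)
}

#' Standard power-study design with planted effects
#'
#' The package's reference configuration for recovery (power) studies: the
#' four major epididymal epithelial clusters at 200 cells per segment per
#' cluster across the default three samples, with ten planted segmental
#' effects (ln fold change 3, target detection 0.4 in the boosted
#' stratum), six planted age effects (ln difference 2, detection 0.7,
#' boosted in P42) and two planted markers per cluster (ln effect 3).
#' Planted genes are spread over clusters and segments deterministically.
#'
#' @param seed Seed stored in the design.
#' @return A [SimDesign-class].
#' @export
#' @examples
#' plantedRecoveryDesign(seed = 3)
plantedRecoveryDesign <- function(seed = 1L) {
  cl4 <- c(principal = 0.25, basal = 0.25, clear_narrow = 0.25,
           halo_T = 0.25)
  segspec <- data.frame(
    gene_id = NA_character_,
    cluster = rep(names(cl4), length.out = 10),
    segment = rep(.SEGMENT_LEVELS, length.out = 10),
    effect = 3, detect_target = 0.4, stringsAsFactors = FALSE)
  agespec <- data.frame(
    gene_id = NA_character_,
    cluster = rep(names(cl4), length.out = 6),
    segment = rep(.SEGMENT_LEVELS, length.out = 6),
    age = "P42", effect = 2, detect_target = 0.7, stringsAsFactors = FALSE)
  mkspec <- data.frame(cluster = names(cl4), n_genes = 2L, effect = 3,
                       detect_target = 0.5, stringsAsFactors = FALSE)
  simDesign(clusterProportions = cl4, cellsPerSegment = 800L,
            nGenes = 300L, clusterMarkerSpec = mkspec,
            segmentalEffectSpec = segspec, ageEffectSpec = agespec,
            rngSeed = as.integer(seed))
}
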