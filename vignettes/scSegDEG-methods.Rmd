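---
title: "Segmental and age-related differential expression in epididymal scRNA-seq: models and methods"
author: "scSegDEG authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmental and age-related differential expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scSegDEG)
```

# Scope and data model

The mouse epididymis is a single convoluted duct that sperm traverse from
the caput (proximal) through the corpus to the cauda (distal) segment, and
its epithelium — principal, basal, clear/narrow, halo/T and supporting cell
populations — expresses genes in strongly segment-dependent patterns.
scSegDEG implements the downstream, rank-test based analysis of a
multi-sample single-cell UMI experiment over such a segmented tissue:
quality control and normalization, marker-panel cluster annotation,
cross-replicate conserved marker calling, segmental differential
expression across caput/corpus/cauda, first-wave (P42) versus adult (P56)
differential expression, and mitochondrial transcript-fraction profiling.
Upstream processing (read alignment, UMI counting, integration,
clustering) is out of scope; cluster labels arrive as input metadata.

The central container is `SegExperiment`, a `SingleCellExperiment` whose
validity enforces the analysis contract: a non-negative integer `counts`
assay (genes × cells), unique gene ids and barcodes, per-cell `sample_id`,
`segment` (caput/corpus/cauda), `age` (P42/P56) and `cluster` columns, and
per-gene `is_mito` / `is_globin` flags. Mitochondrial genes are recognized
by a configurable, case-insensitive id prefix (default `"mt-"`, the mouse
Gencode convention) rather than a hard-coded gene list; globins default to
the five mouse genes commonly removed as erythrocyte contamination
(Hba-a1, Hba-a2, Hba-ps4, Hbb-bs, Hbb-bt).

# Normalization

Expression values are log1pRPM: each cell's counts are scaled to reads per
million of its total UMI and shifted-log transformed with the natural
logarithm,

$$v_{gc} = \ln\!\left(1 + 10^6\,\frac{x_{gc}}{\sum_g x_{gc}}\right),$$

so zeros map exactly to zero and the transform is strictly monotone within
a cell. The RPM denominator is the cell's total after the QC filters
applied so far; the per-step QC log records removal counts so alternative
orderings are recomputable. The base is fixed to $e$ because the segmental
fold-change identity below only holds on that scale.

# Quality control

Defaults in `segParams()`: genes are kept when expressed (UMI > 0) in at
least 3 cells; cells are kept with 300–4000 detected genes. The bounds are
treated as inclusive — the procedure's wording ("between") does not fix
strictness, and inclusivity is the conventional reading, changing results
only at exact boundaries. Filter order is gene floor → cell range → globin
removal → optional cluster exclusion (e.g. an erythrocyte cluster via
`dropCluster()`); gene filtering precedes the cell filter because it
changes detected-gene counts, and the order is logged. No upper
mitochondrial-fraction cell filter is applied by default: the analysis
treats high MT content as signal (it is segment-graded in this tissue),
not as a damage proxy.

# Rank tests

All group comparisons are non-parametric. `wilcoxonRankSum()` uses exact
enumeration when the pooled sample is at most 12 with no ties, otherwise
the normal approximation with midrank tie-corrected variance and
continuity correction; `kruskalWallis()` computes the tie-corrected $H$
and refers it to $\chi^2_{k-1}$. Degenerate all-tied inputs return
$p = 1$. The chi-square reference is an approximation: at very small group
sizes it can differ from the exact permutation distribution of $H$
substantially (for three groups of two, the permutation tail of the
maximal $H$ is 0.067 where the chi-square gives 0.102), which is the
standard behaviour of the test and is documented rather than patched,
since group sizes in practice are tens to hundreds of cells. The batch
row-wise implementations used by the callers reproduce
`stats::kruskal.test` / `stats::wilcox.test` to near machine precision
(verified in the test suite).

Multiple testing uses Bonferroni correction, $p_{\mathrm{adj}} =
\min(1, m\,p)$, with $m$ the number of genes entering the contrast in that
sample — reported alongside the results, since the choice of $m$ is the
one under-determined element of the published procedure.

# Conserved cluster markers

For each sample, the target cluster is compared to all other cells of the
sample per gene (Wilcoxon one-vs-rest on log1pRPM), adjusted by Bonferroni
within the sample, and the per-sample adjusted p values are combined by
their **maximum**; a conserved marker must therefore be significant in
every contributing replicate (combined $p < 0.05$). Samples lacking the
target cluster are skipped with a warning rather than contributing a
pseudo-p. A pre-screen requires 10% of target-cluster cells to express the
gene; the published procedure implies such a floor without printing one,
and 10% matches the convention of the toolkits it used. Genes screened out
in a contributing sample carry adjusted $p = 1$ there, which is
conservative: a gene untestable in one replicate cannot be called
conserved.

# Segmental differential expression

The core procedure, per cell cluster, across the three segments, with all
comparisons strict:

1. **Test** — per sample, Kruskal-Wallis of log1pRPM across segments,
   Bonferroni over all genes entering the test; the combined p is the
   maximum across samples and must be < 0.05.
2. **Expression floor** — per sample, the expressing proportion
   (UMI > 0, a threshold-free count-level quantity) in each segment; the
   sample-level minimum of the segment-highest proportion must be > 0.25.
3. **Effect size** — per sample, the fold change between the extreme
   segments, $\ln\frac{1 + \mathrm{RPM}_{high}}{1 + \mathrm{RPM}_{low}}$,
   where RPM is the segment-level mean of per-cell RPM; the sample-level
   minimum must be > 2 natural-log units (≈ 7.4-fold linear).
4. **Specificity** — only genes passing 1–3 in exactly one cluster are
   retained, the "specifically differentially expressed in one
   population" rule. Genes untestable in a cluster count as non-passing
   there, and the audit table records every intermediate quantity.

RPM means (not per-cell log means) enter the fold change because that is
the only reading under which the defining identity
$\mathrm{log1pRPM}_{high} - \mathrm{log1pRPM}_{low} =
\ln((1+\mathrm{RPM}_{high})/(1+\mathrm{RPM}_{low}))$ holds exactly.
Segments contributing fewer than 3 cells (configurable
`minCellsPerGroup`) to a cluster in a sample are dropped; samples left
with fewer than two segments are skipped with a warning, mirroring the
max-combination's conservative treatment of missing evidence.

# Age-related differential expression

Per cluster × segment stratum, P56 cells are compared to P42 cells with
the two-group Kruskal-Wallis test (identical to the tie-corrected
Wilcoxon without continuity correction), Bonferroni over genes in the
stratum. A call requires, strictly: detection above 50% in at least one
age group, |log1pRPM difference| above 1, and adjusted $p$ below 0.01.
The difference defaults to the difference of age-group means of per-cell
log1pRPM (`ageDiffMethod = "cell_mean"`) — the plain reading of the
procedure, which quotes no RPM-level identity here; the segmental-style
alternative (`"log1p_mean_rpm"`) is available behind the config switch
for sensitivity analysis.

# Mitochondrial transcript profiling

Per cell, the MT fraction is the share of UMIs on prefix-matched genes;
aggregation by any combination of sample, segment, cluster and age gives
means, medians and cell counts, and `compareSegmentsMt()` ranks segments
descriptively (no hypothesis test is attached, matching how such
percentages are reported). Fractions are computed on the QC-filtered
matrix **before** globin removal so the denominators describe retained
cells' full UMI content; the logged filter order makes the alternative
recomputable.

# The synthetic generator

`simulateDataset()` draws UMI counts from a negative binomial with
gene-shared dispersion (size 2) — the minimal overdispersed count model;
nothing parametric is assumed by the rank tests downstream, so the
generator only needs realistic sparsity and overdispersion. Expected
counts are `library_size × p`, with `p` the cell's expression proportion:
log-normal baseline gene weights (sdlog 1.5) times the exponential of
every planted effect applying to the cell's (cluster, segment, age)
stratum. Planted effects are multiplicative on the ln scale, matching the
fold-change definition under test. Mitochondrial weights are rescaled per
stratum so each segment's expected MT fraction hits its target exactly;
the defaults are the P42 profile (caput 7.7%, corpus 17.0%, cauda 13.7%).

The default design mirrors the motivating study's shape at desk scale:
one P42 sample plus two P56 replicates, three segments each, eight
clusters with ~60% principal cells, 300 cells per segment and 500 genes,
log-normal library sizes around 3,000 UMIs. These sizes are the package's
reference conditions for its null-calibration studies; they keep a
20-replicate calibration run in the minutes range while leaving every
cluster ≥ 6 cells per segment.

Planted effects can carry a detection target: the gene's baseline weight
is then solved from the negative-binomial zero probability so the boosted
stratum expresses the gene in roughly the requested fraction of cells.
This matters for two reasons. First, it pins the planted conditions of
the recovery studies (`plantedRecoveryDesign()`: ln-FC 3 segmental
effects at detection 0.4, ln-difference 2 age effects at 0.7, markers at
0.5, four epithelial clusters at 200 cells/segment/cluster). Second, it
keeps planted genes' absolute weights small. Because expression
proportions are compositional, planting a large boost on a
high-baseline gene measurably depresses every other gene's share in that
stratum, and with thousands of cells those induced shifts are genuine,
detectable differential expression — a property of the model, not a test
error. Calibrated baselines keep that compositional footprint negligible
so recovery scores measure the procedure. For the same reason,
`scoreRecovery()` does not count calls on any planted gene as false
discoveries regardless of call type: a segmental boost legitimately makes
its gene a cluster marker too.

What the generator does **not** emulate: ambient RNA, doublets, batch
effects, gene-gene correlation beyond composition, segment-graded library
sizes, or cluster-specific dispersion. Passing null-calibration and
recovery tests on this generator therefore shows the procedure is
correctly implemented and calibrated under clean overdispersed counts; it
does not certify behaviour under real-data artifacts the upstream toolkit
is responsible for removing.

# Numerical and design choices

* **Strictness**: every published threshold is compared strictly
  ("larger than"); boundary values (expressing proportion exactly 0.25,
  fold change exactly 2) fail.
* **Ties in annotation**: `annotateClusters()` breaks score ties
  lexicographically and flags them; all-zero scores give `"unknown"`.
  The argmax-with-audit-table rule operationalizes what is otherwise an
  inspect-by-eye step; the audit matrix preserves the evidence.
* **Tie handling in tests**: midranks throughout; all-tied rows get
  $p = 1$ rather than NaN from a zero tie-corrected variance.
* **Fold-change ties**: `segmentFoldChange()` resolves equal extreme
  means to the first segment in caput/corpus/cauda order,
  deterministically.
* **Degenerate inputs**: empty groups, zero-total cells, missing panel
  genes and absent clusters are errors that name the offending object;
  missing cluster labels in `dropCluster()` warn and no-op.
* **Matrix orientation** is genes × cells with 1-based Matrix Market
  indices on disk; duplicate ids are hard errors, never deduplicated
  silently.
* **Desk-scale QC bounds**: the 300–4000 detected-gene window presumes a
  transcriptome-scale gene space; pipeline runs over the synthetic
  generator's few hundred genes scale the window accordingly (the
  parameter object is the single source for all thresholds, so this is
  one argument).

# Worked example

A three-gene toy: one cell with 1,000 total UMIs and a single count of a
gene gives $\ln(1 + 10^6/10^3) = \ln 1001 \approx 6.9088$ log1pRPM — the
same number as the fold change between segment mean RPMs of 1,000 and 0.

```{r}
sim <- simulateDataset(simDesign(nGenes = 120, cellsPerSegment = 80,
                                 clusterProportions = c(principal = 0.5,
                                                        basal = 0.5)))
sim <- computeLog1pRPM(sim)
degs <- suppressWarnings(callSegmentalDegs(sim))
table(retained = degs$retained_specific)
aggregateMtFractions(sim, "segment")
```

Under this null design nothing should be (and nothing is) retained, and
the segment MT means sit on the 7.7/17.0/13.7% targets.

# Known limitations

* Cluster labels are trusted input; mis-clustering propagates into every
  per-cluster result.
* The max-P combination makes conserved-marker and segmental calls
  conservative in the number of replicates; a single underpowered sample
  can veto a true effect, which is the intended trade-off.
* The Bonferroni scope $m$ (genes per sample-level contrast) follows the
  toolkit convention of the published procedure; other scopes change
  absolute significance calls.
* The chi-square Kruskal-Wallis reference is anti-conservative or
  conservative at very small group sizes, as quantified above; with the
  default `minCellsPerGroup = 3` and realistic cluster sizes this is
  immaterial, but single-digit strata should be interpreted with care.
* The shipped 26-gene marker panel is provisional, assembled from the
  epididymal literature, and intended to be replaced by the user's own
  panel TSV.
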