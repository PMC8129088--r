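# scSegDEG

Rank-test based downstream analysis of segmented single-cell RNA-seq
experiments, built for the mouse epididymis. Sperm mature while moving
from the caput through the corpus to the cauda segment of the epididymal
duct, and the duct's epithelial cell types (principal, basal,
clear/narrow, halo/T and supporting populations) express genes in
strongly segment-dependent — and age-dependent (first sperm wave at P42
vs adult P56) — patterns. scSegDEG turns the bespoke computations such a
study needs into a tested, reusable pipeline for anyone analyzing
multi-sample UMI count data over a spatially segmented tissue.

## What it computes

Given a genes × cells UMI matrix plus per-cell sample, segment, age and
cluster annotations (`SegExperiment`, a validated
`SingleCellExperiment`):

* **QC + normalization** — genes expressed in ≥ 3 cells; cells with
  300–4000 detected genes; globin (erythrocyte contamination) removal;
  `log1pRPM = ln(1 + 1e6 · count / total UMI)`.
* **Cluster annotation** — average log1pRPM of a user-editable marker
  panel per cluster, argmax cell type with a full score audit table.
* **Conserved markers** — per-sample one-vs-rest Wilcoxon rank-sum,
  Bonferroni within sample, combined by the **maximum** adjusted p across
  replicates (significant < 0.05 means significant in *every* sample).
* **Segmental DEGs** — the core procedure, per cluster across
  caput/corpus/cauda: per-sample Kruskal–Wallis with Bonferroni and
  max-P combination (< 0.05), sample-minimal best-segment expressing
  proportion (> 25%), sample-minimal fold change
  `ln((1 + RPM_high)/(1 + RPM_low))` (> 2 natural-log units), and a
  one-cluster specificity rule.
* **Age DEGs** — P56 vs P42 per cluster × segment: detection > 50% in an
  age group, |log1pRPM difference| > 1, adjusted p < 0.01.
* **Mitochondrial profiling** — per-cell MT UMI fraction (`mt-` prefix),
  aggregated by sample/segment/cluster/age, with descriptive segment
  ranking.
* **Synthetic data** — a negative-binomial multi-sample generator with
  planted cluster-marker, segmental and age effects, segment-graded MT
  fraction targets and exported ground truth for recovery scoring.

## Worked example

```r
library(scSegDEG)

# study-shaped synthetic dataset with one planted caput effect
des <- simDesign(
  nGenes = 200, cellsPerSegment = 150,
  clusterProportions = c(principal = 0.5, basal = 0.5),
  segmentalEffectSpec = data.frame(gene_id = NA, cluster = "principal",
                                   segment = "caput", effect = 3,
                                   detect_target = 0.4))
x <- computeLog1pRPM(simulateDataset(des, seed = 13))

degs <- callSegmentalDegs(x)
subset(degs, retained_specific,
       select = c(gene_id, cluster, high_segment, combined_p_adj,
                  min_fold_change, min_best_prop))
#>       gene_id   cluster high_segment combined_p_adj min_fold_change min_best_prop
#> 219 gene00001 principal        caput    1.63847e-06        2.737162     0.3066667

aggregateMtFractions(x, "segment")
#>   segment mean_mt_fraction median_mt_fraction n_cells
#> 1   caput       0.07778136         0.07485531     450
#> 2   cauda       0.13703169         0.13385840     450
#> 3  corpus       0.17148295         0.16910954     450
```

The planted gene is recovered with the right cluster and segment: its
combined (max across the three samples) Bonferroni-adjusted
Kruskal–Wallis p is far below 0.05, the worst-sample fold change of 2.74
natural-log units clears the > 2 rule, and the worst-sample best-segment
expressing proportion 0.31 clears the > 25% rule. The segment MT means
sit on the P42 profile the generator targets (7.7%, 17.0%, 13.7%).

`runPipeline()` chains the stages into TSV outputs with a JSON run
manifest (`inst/scripts/segpipe.R` is a shell wrapper).

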