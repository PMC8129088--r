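Package: scSegDEG
Title: Segmental and Age-Related Differential Expression for Epididymal
    Single-Cell RNA-Seq
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rank-test based downstream analysis of segmented single-cell
    RNA-seq experiments, built for the mouse epididymis (caput, corpus,
    cauda). Provides log1pRPM normalization, gene/cell quality-control
    filters, marker-panel cluster annotation, cross-replicate conserved
    marker detection (Wilcoxon rank-sum, Bonferroni, max-P combination),
    a multi-filter Kruskal-Wallis segmental differential-expression
    procedure with a one-population specificity rule, first-wave (P42)
    versus adult (P56) differential expression, per-cell mitochondrial
    transcript fraction profiling, and a negative-binomial synthetic UMI
    generator with planted effects for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3),
    SingleCellExperiment
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SingleCell, Transcriptomics, DifferentialExpression,
    GeneExpression, QualityControl
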