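Package: tumortalk
Title: Tumor Immune Microenvironment Analysis: Cell Typing, Ligand-Receptor
    Interaction Scoring, and Preclinical Efficacy Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for single-cell profiling of the tumor immune
    microenvironment under checkpoint-modulating treatment. Provides QC,
    depth normalization, graph-based clustering and marker-panel cell-type
    annotation of gene-by-cell count matrices; per-sample cell-composition
    comparison; ligand-receptor interaction scoring by the product of mean
    ligand and mean receptor expression with a label-permutation enrichment
    null and cross-condition conserved-interaction detection; weighted
    tumor-mutational-burden scoring from variant classifications;
    median-split expression stratification, Kaplan-Meier and log-rank
    survival analysis; and caliper-based tumor volume and tumor growth
    inhibition (TGI) computations. A negative-binomial synthetic-cohort
    generator with serialized ground truth supports end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    BiocNeighbors,
    igraph,
    survival,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
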