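---
title: "Methods: scoring tumor-immune crosstalk with tumortalk"
author: "tumortalk maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring tumor-immune crosstalk with tumortalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumortalk)
```

# Scope and model

tumortalk quantifies how a treatment reshapes the tumor immune
microenvironment, using three connected layers of analysis:

1. **Cell typing** of gene-by-cell UMI count matrices: QC, depth
   normalization, PCA + kNN-graph community detection, and marker-panel
   annotation of the resulting clusters.
2. **Crosstalk scoring**: ligand–receptor interaction strength between two
   cell compartments, with a permutation enrichment null and
   conserved-interaction calls across sample groups.
3. **Cohort and preclinical endpoints**: weighted tumor mutational burden,
   median expression stratification, Kaplan–Meier/log-rank survival analysis,
   and caliper-based tumor volume / tumor growth inhibition.

A synthetic-cohort generator with serialized ground truth closes the loop:
every estimator is validated against data whose true structure is known.

# Single-cell processing

## QC and normalization

`qcFilter` retains cells with total counts ≥ `min_counts_per_cell`, detected
genes ≥ `min_genes_per_cell`, and mitochondrial count fraction ≤
`max_mito_fraction`. Defaults (500, 200, 0.2) follow common droplet-data
practice; they are deliberately conservative for real 10x libraries and are
set explicitly in all analyses of synthetic data, whose libraries are
shallower. The filter is idempotent and reports per-criterion tallies; if it
would remove every cell it stops with those tallies rather than returning an
empty object.

`normalizeLog` computes `ln(1 + scale × count / cell_total)` with
`scale = 1e4` (counts per 10k). Mitochondrial content is handled by the QC
fraction filter, not regression: at the cohort sizes targeted here the
fraction filter removes the damaged cells that drive the artifact, and
keeping the transformation a pure per-cell function preserves within-cell
rank order exactly, which the tests assert.

## Clustering

`clusterCells` z-scores each gene (capped at ±10 so no single gene dominates
the metric), takes the top `n_pcs` principal components (default 7), builds a
k-nearest-neighbour graph (Euclidean distance in PC space, `k_neighbors`
default 15) and partitions it with Louvain modularity optimization at a
configurable `resolution`. Cluster labels are contiguous from 0, ordered by
decreasing size with ties broken by lowest community id, and the community
detection is seeded, so a fixed seed gives a fixed partition.

Numerical notes:

* A matrix whose scaled expression is identically zero (all cells identical)
  short-circuits to a single cluster — PCA is undefined there.
* Zero-variance genes are mapped to zero rather than dropped, so the gene
  axis is stable.
* Over-clustering at the default resolution is harmless downstream: several
  clusters of one cell type simply receive the same annotation. Cluster
  *counts* should therefore not be interpreted biologically; the annotated
  types should.

## Annotation

`annotateClusters` scores each cluster against each cell type as the mean
(over the cluster's cells) of the mean log-normalized expression of the
type's marker genes, and assigns the argmax. Exact ties give `"unassigned"`
with a tie flag — reproducibility is preferred over an arbitrary choice.
Markers absent from the gene universe are dropped with a warning; a type with
no present markers is unscoreable. The full score matrix is kept in the
`CellTypeMap` as evidence.

The default panel names the eight microenvironment types by their canonical
markers: cancer (Wnt10a), NK&T (Cd3e), CD8 T (Cd8a), Treg (Foxp3), NK
(Klrb1a), macrophage (C1qc), cDC (H2-Aa), pDC (Klk1b27).

# Interaction scoring

For sender type S, receiver type R and pair (ligand l, receptor r), the
per-sample score is

$$ \mathrm{score} = \overline{x}_{l,S} \times \overline{x}_{r,R}, $$

the product of mean log-normalized ligand expression over S cells and mean
receptor expression over R cells. The product is the only symmetric scalar
combining exactly those two averages; it is bilinear in each factor's mean
and nonnegative on log-normalized data. Scores are computed on normalized
(not scaled) expression so they remain interpretable as co-expression
strength. When either compartment has fewer than `min_cells` cells (default
10) in a sample, the score is *flagged-missing* (`NA`), never 0 — absence of
evidence must not masquerade as evidence of absence when group means are
taken.

## Permutation enrichment null

`permutationSignificance` shuffles cell-type labels across cells — within
sample, when sample ids are supplied, so cohort structure is respected —
recomputes the score B times (default 1000) and reports the add-one estimator

$$ p = \frac{1 + \#\{\mathrm{null} \ge \mathrm{observed}\}}{1 + B}, $$

which is bounded below by 1/(B+1) and super-uniform under exchangeability.
The tests verify calibration empirically: under a label-exchangeable
generator the rejection rate at α = 0.05 lies in [0.03, 0.07] over 500
replicates.

## Group means, conservation, ranking

Per-sample scores are averaged within each (model × condition) group,
excluding flagged-missing samples; a group with no scoreable sample has a
flagged-missing mean. A pair is **conserved** when in *every* group it is
(i) significant at `alpha` (permutation p on the group's pooled cells) and
(ii) expressed — detected in ≥ `min_expressed_frac` (default 10%) of sender
cells for the ligand and receiver cells for the receptor. The expressed gate
prevents conserved calls driven by near-zero means. Because it is ambiguous
whether conservation should require statistical significance or mere
expression in each group, both component flags (`significant_all_groups`,
`expressed_all_groups`) are emitted alongside the combined call.
Benjamini–Hochberg q-values are reported across pairs within each group; the
conserved call uses raw p, and both are available.

`rankInteractions` orders a group's pairs by descending mean score, ties
broken by smaller p, then lexicographic pair id, with flagged-missing means
last.

# Composition analysis

`cellFractions` tallies per-sample type fractions exactly (unassigned cells
are their own category, so fractions sum to 1). `compareFractions` tests a
type's fraction between conditions with a two-sided permutation test on
*per-sample* fractions — the sample, not the cell, is the unit of inference,
because cells within a tumor are not independent. When the number of label
arrangements is ≤ 20,000 the null is enumerated exhaustively (p is then the
exact proportion of arrangements at least as extreme, attaining its minimum
at 2/number-of-arrangements for a mirror-symmetric statistic); otherwise
`n_perm` Monte-Carlo draws with the add-one estimator are used.

# Cohort metrics

* **TMB**: `2 × truncating + 1 × non-truncating`, where truncating =
  {nonsense, frame-shift del/ins, splice-site} and non-truncating =
  {missense, in-frame del/ins, nonstop}; everything else (silent, UTR,
  intron, ...) is excluded from the score. Strings follow MAF conventions,
  matched case-insensitively with a user-extensible synonym table. The score
  is the raw weighted count — no per-megabase normalization, as the defining
  formula has no denominator. Whether silent mutations should instead count
  as non-truncating is unspecified upstream; they are excluded here and the
  classification is logged per record via `classifyMutation`.
* **Stratification**: samples ≥ median are "high", below are "low"; a sample
  exactly at the median goes high, deterministically. Constant vectors error
  (degenerate stratification).
* **Survival**: `kmEstimate` wraps the product-limit estimator
  (survival::survfit) and returns a right-continuous step function;
  `logrankTest` wraps survival::survdiff (χ², 1 df). Tests validate both
  against independently coded oracles — a hand product-limit table and an
  explicit risk-set observed−expected tabulation — and check type-I-error
  calibration under hazard ratio 1. Hazard-ratio estimation and Cox
  regression are out of scope.

# Preclinical efficacy

`tumorVolume` implements V = 0.5·a·b² (mm³) with a ≥ b enforced.
`tgi` computes TGI% = [1 − (TVi − TV0)/(TVvi − TVv0)] × 100 from arm means at
day 0 and the readout day, where day 0 is the first measurement day common to
both arms (the formula's "day 0" is not anchored to a calendar otherwise).
Animals missing either time point are excluded from both means
(complete-case) and reported; TVvi = TVv0 is an explicit undefined-TGI error.
`survivalFromGrowth` thresholds curves at a configurable endpoint volume
(default 2000 mm³) to produce time-to-endpoint records.

# The synthetic-cohort generator

`generateCohort` draws, per sample, cell-type counts from a multinomial over
condition-specific fractions, then gene counts from a negative binomial
(mean–dispersion parameterization) with

mean = baseline × markerFold^(marker or program gene of own type) ×
effect fold(condition, type, gene) × per-cell library factor,

where the library factor is lognormal with configurable CV (mean 1) and a
dedicated mitochondrial gene block exists so QC is exercisable. All
randomness flows from one integer seed through deterministic per-sample
substreams: the same configuration is byte-identical on rerun.

Default study conditions mirror the motivating design: 3 vehicle vs 3
treated samples, 2000 cells each; eight cell types with cancer dominant
(60% vehicle, 50% treated) and CD8⁺ T / NK&T fractions roughly doubling under
treatment; marker fold 10; NB dispersion 0.3; library-size CV 0.2.

Choices worth recording:

* **Gene programs.** Each type elevates its canonical marker *and*
  `program_genes_per_type` (default 5) co-expressed program genes. Cell
  identity in real data is carried by correlated programs of tens to hundreds
  of genes; with a single informative gene per type the between-type
  structure sits below the noise floor of z-scored PCA (the
  Marchenko–Pastur bulk) and no graph clustering could recover it. Five
  program genes is the minimal realistic structure that makes the simulated
  clustering problem comparable in difficulty to real data.
* **Depth.** `baseline_mean = 5` over a ~60–160 gene universe gives
  400–1000 UMI per cell, a realistic shallow droplet library. (Much lower
  settings make log-normalized values essentially ternary and are not
  representative.)
* **Treatment effects are multiplicative on means**, matching fold-change
  language; the default effect table gives Pvr (cancer) and Cd226/Cd96
  (CD8 T) a 3× compartment enrichment in *both* conditions — these genes are
  constitutively expressed by their compartments — and additionally scales
  Pvr and Cd226 up 3× and Cd96 down 0.5× under treatment. Effect magnitudes
  are free parameters (the motivating measurements are reported as bar plots
  without printed folds); they were fixed once at values typical of reported
  checkpoint modulation and are not tuned.
* The generator does **not** attempt doublets, batch effects, spliced/
  unspliced counts, or realistic gene-count scale. Passing tests therefore
  demonstrate correctness of the estimators under the stated generative
  model, not robustness to every artifact of real droplet data.

# Validation strategy and problem sizes

The test suite validates each closed-form operation against independently
coded brute-force oracles (exact to machine precision on 100 random instances
each), each stochastic component against calibration simulations (500
replicates), and the full pipeline against ground truth: coupled-pair
recovery among 50 decoys on cohorts of 4 samples × 2 conditions × 1500 cells
over 20 seeds, and annotation/composition recovery at marker fold 8 with
2000 cells per sample. These sizes were chosen so the whole suite runs in a
few minutes on one CPU while keeping Monte-Carlo error well inside the
asserted bands.

# Known limitations

* Conservation requires significance in every group; with many groups and few
  cells per group this is conservative.
* The permutation null conditions on the observed type proportions; very
  small compartments (< `min_cells`) are flagged-missing rather than tested.
* Exhaustive enumeration in `compareFractions` with ≤ 4 samples per arm
  cannot produce p < 0.1; small designs should be interpreted as estimates
  with uncertainty, not tests.
* TMB here is a weighted count; cross-cohort comparisons at different exome
  sizes need an external normalization.
* The pipeline's subset reanalysis (e.g. re-clustering T cells) reuses the
  same operators on a cell subset; no separate sub-clustering algorithm is
  provided.
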