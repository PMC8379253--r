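#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment assay assays colData rowData assayNames
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

#' Cohort of tumor single-cell count profiles
#'
#' \code{TumorCohort} extends \linkS4class{SingleCellExperiment} with the
#' metadata the downstream analysis requires: every cell carries a
#' \code{sample} identifier and a \code{condition} label (e.g. vehicle vs
#' treated), and mitochondrial genes are flagged in \code{rowData} so QC can
#' compute per-cell mitochondrial fractions.
#'
#' The \code{"counts"} assay holds raw nonnegative integer UMI counts
#' (genes x cells). Normalization adds a \code{"logcounts"} assay.
#'
#' @slot ... inherited from \linkS4class{SingleCellExperiment}.
#' @export
setClass("TumorCohort", contains = "SingleCellExperiment")

setValidity("TumorCohort", function(object) {
    msg <- character()
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "a 'counts' assay is required")
    else {
        cts <- assay(object, "counts")
        if (min(cts) < 0)
            msg <- c(msg, "counts must be nonnegative")
    }
    cd <- colData(object)
    for (col in c("sample", "condition")) {
        if (!col %in% colnames(cd))
            msg <- c(msg, sprintf("colData must contain a '%s' column", col))
        else if (anyNA(cd[[col]]))
            msg <- c(msg, sprintf("colData '%s' must have no missing values", col))
    }
    if (!"is_mito" %in% colnames(rowData(object)))
        msg <- c(msg, "rowData must contain a logical 'is_mito' column")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "cell barcodes must be present and unique")
    if (length(msg)) msg else TRUE
})

#' Construct a TumorCohort
#'
#' @param counts gene x cell matrix of nonnegative integer counts (dense or
#'   \code{dgCMatrix}); rownames are gene identifiers, colnames barcodes.
#' @param sample character vector, one sample id per cell.
#' @param condition character vector, one condition label per cell.
#' @param mito_genes character vector of gene identifiers to flag as
#'   mitochondrial (defaults to the \code{"^mt-"} prefix convention).
#'
#' @return A \linkS4class{TumorCohort}.
#' @export
TumorCohort <- function(counts, sample, condition,
                        mito_genes = grep("^mt-", rownames(counts),
                                          ignore.case = TRUE, value = TRUE)) {
    counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                      "generalMatrix"), "CsparseMatrix")
    if (length(sample) == 1L) sample <- rep(sample, ncol(counts))
    if (length(condition) == 1L) condition <- rep(condition, ncol(counts))
    stopifnot(length(sample) == ncol(counts),
              length(condition) == ncol(counts))
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        colData = DataFrame(sample = as.character(sample),
                            condition = as.character(condition),
                            row.names = colnames(counts)),
        rowData = DataFrame(is_mito = rownames(counts) %in% mito_genes,
                            row.names = rownames(counts)))
    methods::new("TumorCohort", sce)
}

#' @describeIn TumorCohort per-cell sample identifiers.
#' @param x a \code{TumorCohort}.
#' @export
sampleIds <- function(x) colData(x)$sample

#' @describeIn TumorCohort per-cell condition labels.
#' @export
conditionLabels <- function(x) colData(x)$condition

#' @describeIn TumorCohort identifiers of mitochondrial genes.
#' @export
mitoGenes <- function(x) rownames(x)[rowData(x)$is_mito]

#' @describeIn TumorCohort split into one cohort per sample, in first-occurrence
#'   order of the sample labels.
#' @export
splitBySample <- function(x) {
    ids <- unique(sampleIds(x))
    out <- lapply(ids, function(s) x[, sampleIds(x) == s])
    names(out) <- ids
    out
}

setMethod("show", "TumorCohort", function(object) {
    cat("TumorCohort:", nrow(object), "genes x", ncol(object), "cells\n")
    cat("  samples:   ", paste(unique(sampleIds(object)), collapse = ", "), "\n")
    cat("  conditions:", paste(unique(conditionLabels(object)), collapse = ", "), "\n")
    cat("  assays:    ", paste(assayNames(object), collapse = ", "), "\n")
    cat("  mito genes:", sum(rowData(object)$is_mito), "\n")
})

#' Cluster-level cell-type assignment with marker evidence
#'
#' Produced by \code{\link{annotateClusters}}: each retained cell belongs to
#' exactly one cluster, each cluster receives exactly one type label (or
#' \code{"unassigned"} on a tie or when no type is scoreable), and the full
#' per-cluster marker-score table is kept as evidence.
#'
#' @slot barcodes character, one entry per cell.
#' @slot cluster integer cluster ids per cell, contiguous from 0.
#' @slot clusterType character, assigned type per cluster; names are cluster
#'   ids as strings.
#' @slot scores numeric matrix (cluster x type) of mean marker expression.
#' @slot tied logical per cluster: TRUE when the top score was tied.
#' @export
setClass("CellTypeMap", representation(
    barcodes = "character",
    cluster = "integer",
    clusterType = "character",
    scores = "matrix",
    tied = "logical"))

setValidity("CellTypeMap", function(object) {
    msg <- character()
    if (length(object@barcodes) != length(object@cluster))
        msg <- c(msg, "one cluster id per barcode required")
    cl <- sort(unique(object@cluster))
    if (length(cl) && !identical(cl, seq(0L, max(cl))))
        msg <- c(msg, "cluster ids must be contiguous from 0")
    if (!setequal(names(object@clusterType), as.character(cl)))
        msg <- c(msg, "every cluster must map to exactly one type label")
    if (anyNA(object@clusterType))
        msg <- c(msg, "type labels must not be NA (use 'unassigned')")
    if (length(msg)) msg else TRUE
})

#' @describeIn CellTypeMap integer cluster id per cell (named by barcode).
#' @param x a \code{CellTypeMap}.
#' @export
cellClusters <- function(x) stats::setNames(x@cluster, x@barcodes)

#' @describeIn CellTypeMap assigned cell type per cell (named by barcode).
#' @export
cellTypes <- function(x)
    stats::setNames(unname(x@clusterType[as.character(x@cluster)]), x@barcodes)

#' @describeIn CellTypeMap per-cluster marker-score evidence matrix.
#' @export
clusterScores <- function(x) x@scores

#' @describeIn CellTypeMap assigned type per cluster.
#' @export
clusterTypes <- function(x) x@clusterType

setMethod("show", "CellTypeMap", function(object) {
    tab <- table(cellTypes(object))
    cat("CellTypeMap:", length(object@barcodes), "cells in",
        length(object@clusterType), "clusters\n")
    for (ty in names(tab))
        cat(sprintf("  %-12s %d cells\n", ty, tab[[ty]]))
    if (any(object@tied)) cat("  ties:", sum(object@tied), "cluster(s)\n")
})

#' Ligand-receptor interaction analysis results
#'
#' Container returned by \code{\link{interactionAnalysis}} holding, for one
#' (sender type, receiver type) pair of cell types: the per-sample
#' mean-product scores, the per-group (model x condition) mean scores with
#' permutation p-values and BH-adjusted q-values, per-group expressed flags,
#' and the conserved-interaction calls.
#'
#' @slot sender,receiver cell-type labels.
#' @slot perSample data.frame: pair_id, ligand, receptor, sample, score,
#'   ligand_expressed, receptor_expressed (score NA when a type had fewer than
#'   \code{min_cells} cells in that sample: flagged-missing, not zero).
#' @slot perGroup data.frame: pair_id, group, mean_score, n_samples, p, q,
#'   ligand_expressed, receptor_expressed.
#' @slot conserved data.frame: pair_id, significant_all_groups,
#'   expressed_all_groups, conserved.
#' @slot alpha significance level used for the conserved calls.
#' @export
setClass("InteractionResults", representation(
    sender = "character",
    receiver = "character",
    perSample = "data.frame",
    perGroup = "data.frame",
    conserved = "data.frame",
    alpha = "numeric"))

setValidity("InteractionResults", function(object) {
    msg <- character()
    p <- object@perGroup$p
    if (length(p) && any(!is.na(p) & (p <= 0 | p > 1)))
        msg <- c(msg, "permutation p-values must lie in (0, 1]")
    if (!all(object@conserved$pair_id %in% object@perSample$pair_id))
        msg <- c(msg, "conserved table refers to unknown pair ids")
    if (length(object@alpha) != 1L || object@alpha < 0 || object@alpha > 1)
        msg <- c(msg, "alpha must be a single value in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' @describeIn InteractionResults per-sample score table.
#' @param x an \code{InteractionResults}.
#' @export
sampleScores <- function(x) x@perSample

#' @describeIn InteractionResults per-group summary (means, p, q, flags).
#' @export
groupSummary <- function(x) x@perGroup

#' @describeIn InteractionResults conserved-interaction calls.
#' @export
conservedPairs <- function(x) x@conserved

setMethod("show", "InteractionResults", function(object) {
    cat("InteractionResults:", object@sender, "->", object@receiver, "\n")
    cat("  pairs:", length(unique(object@perSample$pair_id)),
        " samples:", length(unique(object@perSample$sample)),
        " groups:", length(unique(object@perGroup$group)), "\n")
    cat("  conserved (alpha =", object@alpha, "):",
        sum(object@conserved$conserved), "pair(s)\n")
    if (any(object@conserved$conserved))
        cat("   ", paste(object@conserved$pair_id[object@conserved$conserved],
                         collapse = ", "), "\n")
})
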