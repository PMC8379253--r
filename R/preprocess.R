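#' QC thresholds
#'
#' @param min_counts_per_cell minimum total UMI counts for a cell to be kept.
#' @param min_genes_per_cell minimum number of detected genes.
#' @param max_mito_fraction maximum fraction of counts in mitochondrial genes,
#'   in [0, 1].
#' @return validated list of thresholds.
#' @export
qcThresholds <- function(min_counts_per_cell = 500L,
                         min_genes_per_cell = 200L,
                         max_mito_fraction = 0.2) {
    if (max_mito_fraction < 0 || max_mito_fraction > 1)
        stop("max_mito_fraction must lie in [0, 1]")
    if (min_counts_per_cell < 0 || min_genes_per_cell < 0)
        stop("count/gene thresholds must be nonnegative")
    structure(list(min_counts_per_cell = min_counts_per_cell,
                   min_genes_per_cell = min_genes_per_cell,
                   max_mito_fraction = max_mito_fraction),
              class = "qc_thresholds")
}

#' Filter low-quality cells
#'
#' Keeps cells with total counts >= \code{min_counts_per_cell}, detected genes
#' >= \code{min_genes_per_cell} and mitochondrial count fraction <=
#' \code{max_mito_fraction}. The gene axis is unchanged. Per-criterion removal
#' tallies are stored in \code{metadata(result)$qc_tally}. Idempotent.
#'
#' @param cohort a \linkS4class{TumorCohort}.
#' @param thresholds a \code{\link{qcThresholds}} object.
#' @return the filtered \code{TumorCohort}.
#' @export
qcFilter <- function(cohort, thresholds = qcThresholds()) {
    stopifnot(methods::is(cohort, "TumorCohort"),
              inherits(thresholds, "qc_thresholds"))
    cts <- assay(cohort, "counts")
    total <- Matrix::colSums(cts)
    ngene <- Matrix::colSums(cts > 0)
    mito <- rowData(cohort)$is_mito
    mito_frac <- if (any(mito))
        Matrix::colSums(cts[mito, , drop = FALSE]) / pmax(total, 1)
    else rep(0, ncol(cts))
    pass_counts <- total >= thresholds$min_counts_per_cell
    pass_genes <- ngene >= thresholds$min_genes_per_cell
    pass_mito <- mito_frac <= thresholds$max_mito_fraction
    keep <- pass_counts & pass_genes & pass_mito
    tally <- c(low_counts = sum(!pass_counts),
               few_genes = sum(!pass_genes),
               high_mito = sum(!pass_mito),
               removed = sum(!keep), retained = sum(keep))
    if (!any(keep))
        stop("qcFilter removed every cell (low_counts=", tally["low_counts"],
             ", few_genes=", tally["few_genes"],
             ", high_mito=", tally["high_mito"], ")")
    out <- cohort[, keep]
    metadata(out)$qc_tally <- tally
    out
}

# log1p depth normalization of a counts matrix; core of normalizeLog.
logNormalizeMatrix <- function(counts, scale = 1e4) {
    total <- Matrix::colSums(counts)
    if (any(total == 0)) {
        bad <- colnames(counts)[total == 0]
        stop("cells with zero total counts cannot be normalized: ",
             paste(utils::head(bad, 5), collapse = ", "))
    }
    log1p(counts %*% Matrix::Diagonal(x = scale / total))
}

#' Depth-normalize and log-transform counts
#'
#' Adds a \code{"logcounts"} assay with
#' \code{ln(1 + scale * count / cell_total)} — the standard per-10k depth
#' scaling followed by log1p. Monotone in counts within each cell.
#'
#' @param cohort a \linkS4class{TumorCohort} (after QC, so no zero-total cell).
#' @param scale library-size scale factor (default 1e4).
#' @return the cohort with a \code{logcounts} assay added.
#' @export
normalizeLog <- function(cohort, scale = 1e4) {
    stopifnot(methods::is(cohort, "TumorCohort"))
    lc <- logNormalizeMatrix(assay(cohort, "counts"), scale)
    dimnames(lc) <- dimnames(cohort)
    SummarizedExperiment::assay(cohort, "logcounts") <- lc
    cohort
}

# Per-gene z-score with winsorization; genes with zero variance map to 0.
scaleGenes <- function(expr, cap = 10) {
    x <- as.matrix(expr)
    mu <- rowMeans(x)
    sd <- apply(x, 1, stats::sd)
    sd[sd == 0] <- Inf
    z <- (x - mu) / sd
    z[z > cap] <- cap
    z[z < -cap] <- -cap
    z
}

#' Graph-based clustering of cells
#'
#' Scales each gene (z-score capped at +/-10), takes the top principal
#' components of the scaled log-expression, builds a k-nearest-neighbour
#' graph (Euclidean distance in PC space) and partitions it with Louvain
#' modularity community detection. Cluster ids are relabeled contiguously
#' from 0 in decreasing cluster-size order (ties by lowest community id).
#'
#' @param x a \linkS4class{TumorCohort} with a \code{logcounts} assay, or a
#'   genes x cells expression matrix.
#' @param n_pcs number of principal components (default 7).
#' @param k_neighbors neighbours for the kNN graph (default 15, minimum 2).
#' @param resolution Louvain resolution parameter.
#' @param seed integer seed (community detection is seeded for determinism).
#' @return integer vector of 0-based cluster ids, named by cell barcode.
#' @export
clusterCells <- function(x, n_pcs = 7L, k_neighbors = 15L, resolution = 1,
                         seed = 1L) {
    expr <- if (methods::is(x, "TumorCohort")) {
        if (!"logcounts" %in% assayNames(x))
            stop("run normalizeLog() first: no 'logcounts' assay")
        assay(x, "logcounts")
    } else x
    ncell <- ncol(expr)
    if (k_neighbors < 2L) stop("k_neighbors must be >= 2")
    if (ncell < k_neighbors + 1L)
        stop("need at least k_neighbors + 1 cells (have ", ncell, ")")
    z <- scaleGenes(expr)
    if (all(z == 0)) # all cells identical: a single cluster
        return(stats::setNames(rep(0L, ncell), colnames(expr)))
    n_pcs <- min(n_pcs, nrow(z), ncell)
    pcs <- stats::prcomp(t(z), center = TRUE, scale. = FALSE,
                         rank. = n_pcs)$x
    knn <- BiocNeighbors::findKNN(pcs, k = k_neighbors)
    edges <- cbind(rep(seq_len(ncell), k_neighbors), as.vector(knn$index))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::simplify(g)
    set.seed(seed)
    comm <- igraph::cluster_louvain(g, resolution = resolution)
    memb <- igraph::membership(comm)
    # contiguous 0-based ids, largest community first, ties by lowest id
    sizes <- table(memb)
    ord <- order(-as.vector(sizes), as.integer(names(sizes)))
    relabel <- stats::setNames(seq_along(ord) - 1L, names(sizes)[ord])
    stats::setNames(unname(relabel[as.character(memb)]), colnames(expr))
}

#' Annotate clusters with cell types from a marker panel
#'
#' For each cluster and candidate type, the score is the mean (over the
#' cluster's cells) of the mean log-normalized expression of that type's
#' marker genes; the assigned type is the argmax. Markers missing from the
#' gene universe are dropped with a warning; a type with no present marker is
#' unscoreable (NA). Exact ties yield \code{"unassigned"} with a tie flag.
#'
#' @param x a \linkS4class{TumorCohort} with \code{logcounts}, or a genes x
#'   cells expression matrix.
#' @param clusters integer cluster ids per cell (from
#'   \code{\link{clusterCells}}).
#' @param panel named list: cell type -> marker genes.
#' @return a \linkS4class{CellTypeMap}.
#' @export
annotateClusters <- function(x, clusters, panel) {
    expr <- if (methods::is(x, "TumorCohort")) assay(x, "logcounts") else x
    stopifnot(length(clusters) == ncol(expr))
    if (anyDuplicated(names(panel))) stop("duplicate cell types in panel")
    barcodes <- colnames(expr)
    cl_ids <- sort(unique(as.integer(clusters)))
    missing <- setdiff(unlist(panel), rownames(expr))
    if (length(missing))
        warning("markers absent from gene universe: ",
                paste(missing, collapse = ", "))
    # per-cell marker score for each type = mean expression of present markers
    cell_scores <- vapply(panel, function(mk) {
        mk <- intersect(mk, rownames(expr))
        if (!length(mk)) return(rep(NA_real_, ncol(expr)))
        Matrix::colMeans(expr[mk, , drop = FALSE])
    }, numeric(ncol(expr)))
    scores <- t(vapply(cl_ids, function(ci) {
        colMeans(cell_scores[as.integer(clusters) == ci, , drop = FALSE])
    }, numeric(length(panel))))
    dimnames(scores) <- list(as.character(cl_ids), names(panel))
    assign_one <- function(row) {
        if (all(is.na(row))) return(c("unassigned", "no_tie"))
        best <- max(row, na.rm = TRUE)
        winners <- names(row)[!is.na(row) & row == best]
        if (length(winners) > 1) c("unassigned", "tie") else c(winners, "no_tie")
    }
    res <- apply(scores, 1, assign_one)
    methods::new("CellTypeMap",
                 barcodes = barcodes,
                 cluster = as.integer(clusters),
                 clusterType = stats::setNames(res[1, ], as.character(cl_ids)),
                 scores = scores,
                 tied = stats::setNames(res[2, ] == "tie", as.character(cl_ids)))
}
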