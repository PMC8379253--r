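#' Write a 10x-style MTX triplet
#'
#' Writes \code{matrix.mtx} (MatrixMarket, 1-based indices), \code{genes.tsv}
#' and \code{barcodes.tsv} into a directory. Internal representation is
#' 0-based/R-native; 1-based indices appear only at the MatrixMarket boundary
#' (handled by \code{Matrix::writeMM}).
#'
#' @param counts gene x cell sparse count matrix with dimnames.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeMtxTriplet <- function(counts, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                    file.path(dir, "matrix.mtx"))
    writeLines(as.character(rownames(counts)), file.path(dir, "genes.tsv"))
    writeLines(as.character(colnames(counts)), file.path(dir, "barcodes.tsv"))
    invisible(dir)
}

#' Read a 10x-style MTX triplet
#'
#' @param dir directory containing \code{matrix.mtx}, \code{genes.tsv},
#'   \code{barcodes.tsv}.
#' @return gene x cell \code{dgCMatrix} with gene/barcode dimnames.
#' @export
readMtxTriplet <- function(dir) {
    paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
    miss <- paths[!file.exists(paths)]
    if (length(miss)) stop("missing file(s): ", paste(miss, collapse = ", "))
    m <- methods::as(Matrix::readMM(paths[1]), "CsparseMatrix")
    if (nrow(m) == 0 || ncol(m) == 0)
        stop("empty matrix in ", paths[1])
    genes <- readLines(paths[2])
    barcodes <- readLines(paths[3])
    if (length(genes) != nrow(m))
        stop("genes.tsv has ", length(genes), " entries but matrix.mtx has ",
             nrow(m), " rows (", dir, ")")
    if (length(barcodes) != ncol(m))
        stop("barcodes.tsv has ", length(barcodes),
             " entries but matrix.mtx has ", ncol(m), " columns (", dir, ")")
    if (anyDuplicated(barcodes))
        stop("duplicate barcodes in ", paths[3])
    dimnames(m) <- list(genes, barcodes)
    m
}

#' Write a cohort as per-sample MTX triplets
#'
#' One subdirectory per sample (matrix.mtx, genes.tsv, barcodes.tsv), a
#' \code{cells.tsv} metadata table (barcode, sample, condition, and true_type
#' when ground truth is supplied) and, optionally, \code{truth.json}.
#'
#' @param cohort a \linkS4class{TumorCohort}.
#' @param dir output directory.
#' @param truth optional ground-truth list from \code{\link{generateCohort}}.
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir, truth = NULL) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (s in unique(sampleIds(cohort)))
        writeMtxTriplet(assay(cohort, "counts")[, sampleIds(cohort) == s,
                                                drop = FALSE],
                        file.path(dir, s))
    meta <- data.frame(barcode = colnames(cohort),
                       sample = sampleIds(cohort),
                       condition = conditionLabels(cohort),
                       stringsAsFactors = FALSE)
    if (!is.null(truth))
        meta$true_type <- unname(truth$cell_types[meta$barcode])
    utils::write.table(meta, file.path(dir, "cells.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(truth)) {
        tr <- truth
        tr$cell_types <- as.list(tr$cell_types)
        jsonlite::write_json(tr, file.path(dir, "truth.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    invisible(dir)
}

#' Read a cohort written by \code{\link{writeCohort}}
#'
#' @param dir directory with per-sample MTX triplets and \code{cells.tsv}.
#' @return a \linkS4class{TumorCohort}.
#' @export
readCohort <- function(dir) {
    meta_path <- file.path(dir, "cells.tsv")
    if (!file.exists(meta_path)) stop("missing cells.tsv in ", dir)
    meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
    mats <- lapply(unique(meta$sample), function(s)
        readMtxTriplet(file.path(dir, s)))
    counts <- do.call(cbind, mats)
    counts <- counts[, meta$barcode, drop = FALSE]
    TumorCohort(counts, meta$sample, meta$condition)
}

pipelineDefaults <- function() {
    list(input_dir = NULL,
         sim = NULL,                      # args for simConfig(); NULL = load
         out_dir = NULL,
         min_counts = 0L, min_genes = 0L, max_mito = 1.0,
         n_pcs = 7L, k_neighbors = 15L, resolution = 1,
         marker_panel = NULL,             # NULL = defaultMarkerPanel()
         pairs = NULL,                    # data.frame or CSV path; NULL = demo
         sender = "cancer", receiver = "CD8T",
         min_cells = 10L, min_expressed_frac = 0.10,
         B = 1000L, alpha = 0.05,
         seed = 1L)
}

#' Validate a pipeline configuration
#'
#' Fills defaults and rejects unknown keys. Configurations may be given as a
#' list or as a YAML/JSON file path.
#'
#' @param config list or path to a YAML/JSON file.
#' @return complete configuration list.
#' @export
pipelineConfig <- function(config = list()) {
    if (is.character(config)) {
        config <- if (grepl("[.]json$", config))
            jsonlite::read_json(config, simplifyVector = TRUE)
        else yaml::read_yaml(config)
    }
    defaults <- pipelineDefaults()
    unknown <- setdiff(names(config), names(defaults))
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    out <- utils::modifyList(defaults, config)
    if (is.null(out$sim) && is.null(out$input_dir))
        stop("config must provide either 'sim' (simulate) or 'input_dir' (load)")
    out
}

runStage <- function(stage, out_dir, fn) {
    tryCatch(fn(), error = function(e) {
        if (!is.null(out_dir)) {
            dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
            writeLines(c(stage, conditionMessage(e)),
                       file.path(out_dir, "FAILED"))
        }
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)
    })
}

#' Run the end-to-end analysis pipeline
#'
#' simulate-or-load -> QC -> normalize -> cluster -> annotate -> cell-type
#' fractions -> interaction scoring with permutation significance ->
#' conserved-interaction calls. All stage outputs are returned; when
#' \code{out_dir} is set, \code{fractions.csv}, \code{interactions.csv}, a
#' circos-ready \code{edges.csv} (sender, receiver, pair, group mean,
#' -log10 p) and a \code{manifest.json} (config and seed) are written. Reruns
#' with the same configuration are bit-identical.
#'
#' @param config list or YAML/JSON path; see \code{\link{pipelineConfig}}.
#' @return list(cohort, cell_type_map, fractions, interactions, truth,
#'   config).
#' @export
runPipeline <- function(config = list()) {
    cfg <- pipelineConfig(config)
    out <- cfg$out_dir
    truth <- NULL
    cohort <- runStage("input", out, function() {
        if (!is.null(cfg$sim)) {
            sim <- do.call(simConfig, c(cfg$sim, list(seed = cfg$seed)))
            res <- generateCohort(sim)
            truth <<- res$truth
            res$cohort
        } else readCohort(cfg$input_dir)
    })
    cohort <- runStage("qc", out, function()
        qcFilter(cohort, qcThresholds(cfg$min_counts, cfg$min_genes,
                                      cfg$max_mito)))
    cohort <- runStage("normalize", out, function() normalizeLog(cohort))
    clusters <- runStage("cluster", out, function()
        clusterCells(cohort, n_pcs = cfg$n_pcs, k_neighbors = cfg$k_neighbors,
                     resolution = cfg$resolution, seed = cfg$seed))
    panel <- if (is.null(cfg$marker_panel)) defaultMarkerPanel()
             else cfg$marker_panel
    ctm <- runStage("annotate", out, function()
        annotateClusters(cohort, clusters, panel))
    fractions <- runStage("fractions", out, function()
        cellFractions(ctm, sampleIds(cohort), conditionLabels(cohort)))
    pairs <- if (is.null(cfg$pairs)) demoLRPairs()
             else if (is.character(cfg$pairs)) readLRPairs(cfg$pairs)
             else validateLRPairs(cfg$pairs)
    inter <- runStage("interactions", out, function()
        interactionAnalysis(cohort, ctm, pairs, cfg$sender, cfg$receiver,
                            B = cfg$B, alpha = cfg$alpha, seed = cfg$seed,
                            min_cells = cfg$min_cells,
                            min_expressed_frac = cfg$min_expressed_frac))
    if (!is.null(out)) {
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(fractions, file.path(out, "fractions.csv"),
                         row.names = FALSE)
        summ <- merge(groupSummary(inter), conservedPairs(inter),
                      by = "pair_id", sort = FALSE)
        summ$sender <- cfg$sender
        summ$receiver <- cfg$receiver
        summ <- summ[order(summ$group, summ$pair_id), ]
        utils::write.csv(summ, file.path(out, "interactions.csv"),
                         row.names = FALSE)
        edges <- data.frame(sender = cfg$sender, receiver = cfg$receiver,
                            pair_id = summ$pair_id, group = summ$group,
                            mean_score = summ$mean_score,
                            neg_log10_p = -log10(summ$p))
        utils::write.csv(edges, file.path(out, "edges.csv"),
                         row.names = FALSE)
        manifest <- list(config = cfg[!vapply(cfg, is.null, logical(1))],
                         seed = cfg$seed,
                         n_cells = ncol(cohort), n_genes = nrow(cohort))
        jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        unlink(file.path(out, "FAILED"))
    }
    list(cohort = cohort, cell_type_map = ctm, fractions = fractions,
         interactions = inter, truth = truth, config = cfg)
}
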