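#' Default marker panel for the mouse CRC tumor microenvironment
#'
#' Eight cell types with the canonical marker genes used to annotate them:
#' cancer cells (Wnt10a), NK&T (Cd3e), CD8 T (Cd8a), Treg (Foxp3), NK
#' (Klrb1a), macrophage (C1qc), classical DC (H2-Aa) and plasmacytoid DC
#' (Klk1b27).
#'
#' @return named list: cell type -> character vector of marker genes.
#' @export
defaultMarkerPanel <- function() {
    list(cancer     = "Wnt10a",
         NKT        = "Cd3e",
         CD8T       = "Cd8a",
         Treg       = "Foxp3",
         NK         = "Klrb1a",
         macrophage = "C1qc",
         cDC        = "H2-Aa",
         pDC        = "Klk1b27")
}

#' Demo ligand-receptor pair table
#'
#' A small demonstration list of checkpoint and chemokine axes relevant to
#' tumor-T cell crosstalk: Pvr (CD155) with its costimulatory (Cd226) and
#' inhibitory (Cd96, Tigit) receptors, plus Tgfb1-Tgfbr1, Il15-Il15ra and
#' Ccl4-Ccr5.
#'
#' @return data.frame with columns pair_id, ligand, receptor.
#' @export
demoLRPairs <- function() {
    data.frame(
        pair_id  = c("Pvr_Cd226", "Pvr_Cd96", "Pvr_Tigit",
                     "Tgfb1_Tgfbr1", "Il15_Il15ra", "Ccl4_Ccr5"),
        ligand   = c("Pvr", "Pvr", "Pvr", "Tgfb1", "Il15", "Ccl4"),
        receptor = c("Cd226", "Cd96", "Tigit", "Tgfbr1", "Il15ra", "Ccr5"),
        stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defines a synthetic two-condition cohort mirroring the study design:
#' multi-sample vehicle vs treated tumors, a cell-type mixture over the eight
#' microenvironment types, marker genes upregulated in their own type, and
#' multiplicative treatment effects on selected genes in selected types
#' (by default: Pvr up in cancer cells, Cd226 up and Cd96 down in CD8 T cells
#' under treatment). Counts are negative binomial with per-cell lognormal
#' library-size factors; a dedicated mitochondrial gene block supports QC.
#'
#' @slot nSamplesPerCondition samples simulated per condition.
#' @slot nCellsPerSample cells per sample.
#' @slot cellTypeFractions list: condition -> named fractions summing to 1.
#' @slot markerPanel list: cell type -> marker genes.
#' @slot baselineMean expected counts of a background gene (per unit library).
#' @slot markerFold fold-up of a marker gene within its own type.
#' @slot effectTable data.frame(condition, cell_type, gene, fold) of
#'   multiplicative treatment effects.
#' @slot dispersion negative-binomial overdispersion (1/size).
#' @slot librarySizeCV coefficient of variation of per-cell library factors.
#' @slot mitoGeneCount number of mitochondrial genes simulated.
#' @slot nBackgroundGenes number of unstructured background genes.
#' @slot programGenesPerType additional co-expressed program genes per cell
#'   type, elevated by the same fold as the canonical marker: cell identity in
#'   real data is carried by correlated gene programs, not single genes.
#' @slot seed master seed; all per-sample substreams derive from it.
#' @export
setClass("SimConfig", representation(
    nSamplesPerCondition = "integer",
    nCellsPerSample = "integer",
    cellTypeFractions = "list",
    markerPanel = "list",
    baselineMean = "numeric",
    markerFold = "numeric",
    effectTable = "data.frame",
    dispersion = "numeric",
    librarySizeCV = "numeric",
    mitoGeneCount = "integer",
    nBackgroundGenes = "integer",
    programGenesPerType = "integer",
    seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    for (cond in names(object@cellTypeFractions)) {
        fr <- object@cellTypeFractions[[cond]]
        if (abs(sum(fr) - 1) > 1e-9)
            msg <- c(msg, sprintf("fractions for '%s' must sum to 1", cond))
        if (any(fr < 0 | fr > 1))
            msg <- c(msg, sprintf("fractions for '%s' must lie in [0,1]", cond))
        if (!setequal(names(fr), names(object@markerPanel)))
            msg <- c(msg, sprintf("fractions for '%s' must cover the marker panel types", cond))
    }
    if (object@baselineMean <= 0) msg <- c(msg, "baselineMean must be > 0")
    if (object@markerFold <= 0) msg <- c(msg, "markerFold must be > 0")
    if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
    if (object@librarySizeCV < 0) msg <- c(msg, "librarySizeCV must be >= 0")
    if (nrow(object@effectTable)) {
        need <- c("condition", "cell_type", "gene", "fold")
        if (!all(need %in% colnames(object@effectTable)))
            msg <- c(msg, "effectTable needs columns condition, cell_type, gene, fold")
        else if (any(object@effectTable$fold <= 0))
            msg <- c(msg, "effect folds must be strictly positive")
    }
    if (object@nSamplesPerCondition < 1L || object@nCellsPerSample < 1L)
        msg <- c(msg, "sample and cell counts must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Default treatment-effect table
#'
#' Pvr (CD155) is expressed by cancer cells and Cd226/Cd96 by CD8 T cells in
#' both conditions (\code{baseline_enrichment} over background); treatment
#' additionally raises Pvr and Cd226 and lowers Cd96 by the given folds.
#' Fold magnitudes are free parameters of the simulation (chosen once; see
#' the methods vignette).
#'
#' @param pvr_fold,cd226_fold,cd96_fold multiplicative treated-vs-vehicle
#'   fold changes.
#' @param baseline_enrichment fold-up of each gene in its own compartment,
#'   present in both conditions.
#' @return data.frame(condition, cell_type, gene, fold).
#' @export
defaultEffectTable <- function(pvr_fold = 3, cd226_fold = 3, cd96_fold = 0.5,
                               baseline_enrichment = 3) {
    base <- data.frame(
        condition = "vehicle",
        cell_type = c("cancer", "CD8T", "CD8T"),
        gene      = c("Pvr", "Cd226", "Cd96"),
        fold      = baseline_enrichment,
        stringsAsFactors = FALSE)
    treated <- transform(base, condition = "treated",
                         fold = baseline_enrichment *
                             c(pvr_fold, cd226_fold, cd96_fold))
    rbind(base, treated)
}

#' @describeIn SimConfig constructor with study-design defaults: 3 vehicle vs
#'   3 treated samples, 2000 cells each, the eight-type marker panel, and the
#'   default checkpoint effect table.
#' @param n_samples_per_condition,n_cells_per_sample cohort dimensions.
#' @param cell_type_fractions list: condition -> named numeric fractions.
#' @param marker_panel list: type -> marker genes.
#' @param baseline_mean,marker_fold,dispersion,library_size_cv count-model
#'   parameters.
#' @param effect_table data.frame(condition, cell_type, gene, fold).
#' @param mito_gene_count,n_background_genes gene-universe composition.
#' @param program_genes_per_type co-expressed identity-program genes per type.
#' @param seed master seed (integer).
#' @export
simConfig <- function(n_samples_per_condition = 3L,
                      n_cells_per_sample = 2000L,
                      cell_type_fractions = list(
                          vehicle = c(cancer = 0.60, macrophage = 0.14,
                                      CD8T = 0.05, NKT = 0.05, Treg = 0.05,
                                      NK = 0.04, cDC = 0.05, pDC = 0.02),
                          treated = c(cancer = 0.50, macrophage = 0.13,
                                      CD8T = 0.10, NKT = 0.09, Treg = 0.04,
                                      NK = 0.04, cDC = 0.07, pDC = 0.03)),
                      marker_panel = defaultMarkerPanel(),
                      baseline_mean = 5,
                      marker_fold = 10,
                      effect_table = defaultEffectTable(),
                      dispersion = 0.3,
                      library_size_cv = 0.2,
                      mito_gene_count = 5L,
                      n_background_genes = 40L,
                      program_genes_per_type = 5L,
                      seed = 1L) {
    methods::new("SimConfig",
        nSamplesPerCondition = as.integer(n_samples_per_condition),
        nCellsPerSample = as.integer(n_cells_per_sample),
        cellTypeFractions = cell_type_fractions,
        markerPanel = marker_panel,
        baselineMean = baseline_mean,
        markerFold = marker_fold,
        effectTable = effect_table,
        dispersion = dispersion,
        librarySizeCV = library_size_cv,
        mitoGeneCount = as.integer(mito_gene_count),
        nBackgroundGenes = as.integer(n_background_genes),
        programGenesPerType = as.integer(program_genes_per_type),
        seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nSamplesPerCondition, "sample(s) x",
        length(object@cellTypeFractions), "condition(s),",
        object@nCellsPerSample, "cells each\n")
    cat("  types:", paste(names(object@markerPanel), collapse = ", "), "\n")
    cat("  baseline mean", object@baselineMean, "| marker fold",
        object@markerFold, "| dispersion", object@dispersion, "\n")
    cat("  effects:", nrow(object@effectTable), "| seed", object@seed, "\n")
})

# Identity-program genes co-expressed with each type's canonical markers.
simProgramPanel <- function(config) {
    if (config@programGenesPerType < 1L)
        return(stats::setNames(vector("list", length(config@markerPanel)),
                               names(config@markerPanel)))
    lapply(stats::setNames(nm = names(config@markerPanel)), function(ty)
        sprintf("%s.prog%d", ty, seq_len(config@programGenesPerType)))
}

# Gene universe: markers + programs + effect genes + decoys + background + mito.
simGeneUniverse <- function(config, extra_genes = character()) {
    markers <- unique(c(unlist(config@markerPanel),
                        unlist(simProgramPanel(config))))
    eff <- unique(config@effectTable$gene)
    bg <- if (config@nBackgroundGenes > 0)
        sprintf("Bg%03d", seq_len(config@nBackgroundGenes)) else character()
    mito <- if (config@mitoGeneCount > 0)
        sprintf("mt-Sim%d", seq_len(config@mitoGeneCount)) else character()
    unique(c(markers, eff, setdiff(extra_genes, c(markers, eff)), bg, mito))
}

# Expected count (per unit library factor) of each gene in each cell type
# under one condition: baseline x marker fold (own type) x effect fold.
simMeanMatrix <- function(config, genes, condition) {
    types <- names(config@markerPanel)
    mu <- matrix(config@baselineMean, nrow = length(genes), ncol = length(types),
                 dimnames = list(genes, types))
    prog <- simProgramPanel(config)
    for (ty in types) {
        mk <- intersect(c(config@markerPanel[[ty]], prog[[ty]]), genes)
        mu[mk, ty] <- mu[mk, ty] * config@markerFold
    }
    eff <- config@effectTable
    if (nrow(eff)) {
        eff <- eff[eff$condition == condition & eff$gene %in% genes &
                   eff$cell_type %in% types, , drop = FALSE]
        for (i in seq_len(nrow(eff)))
            mu[eff$gene[i], eff$cell_type[i]] <-
                mu[eff$gene[i], eff$cell_type[i]] * eff$fold[i]
    }
    mu
}

#' Generate a synthetic multi-sample cohort with ground truth
#'
#' Draws, for each sample, cell types from a multinomial over the configured
#' condition-specific fractions, then gene counts from a negative binomial
#' with mean = baseline x marker fold (markers in their own type) x treatment
#' effect fold x per-cell lognormal library factor. All randomness derives
#' deterministically from \code{config@seed} via per-sample substreams, so the
#' same configuration always yields byte-identical matrices.
#'
#' @param config a \code{\link{simConfig}} object.
#' @param extra_genes additional (background-behaved) gene names to include in
#'   the universe, e.g. decoy ligand/receptor genes.
#' @return list with elements \code{cohort} (a \linkS4class{TumorCohort}
#'   containing all samples) and \code{truth} (list: \code{cell_types} named
#'   per-cell vector, \code{sample_fractions} data.frame of realized per-sample
#'   type fractions, \code{effects} the effect table, \code{coupled_pairs}
#'   effect-table genes annotated by target cell type).
#' @export
generateCohort <- function(config, extra_genes = character()) {
    methods::validObject(config)
    genes <- simGeneUniverse(config, extra_genes)
    conds <- names(config@cellTypeFractions)
    sigma <- sqrt(log(1 + config@librarySizeCV^2))
    size <- 1 / config@dispersion

    mats <- list(); metas <- list(); truth_types <- character(); fr_rows <- list()
    si <- 0L
    for (cond in conds) {
        mu_ty <- simMeanMatrix(config, genes, cond)
        for (r in seq_len(config@nSamplesPerCondition)) {
            si <- si + 1L
            sample_id <- sprintf("%s_%d", cond, r)
            # per-sample substream; offsets keep the derived seed < 2^31
            set.seed((config@seed %% 1000000L) * 1009L + si * 7919L)
            frac <- config@cellTypeFractions[[cond]]
            ncell <- config@nCellsPerSample
            ncts <- as.vector(stats::rmultinom(1, ncell, frac))
            types <- rep(names(frac), ncts)
            lib <- if (sigma > 0)
                stats::rlnorm(ncell, meanlog = -sigma^2 / 2, sdlog = sigma)
            else rep(1, ncell)
            mu <- mu_ty[, types, drop = FALSE] *
                matrix(lib, nrow = length(genes), ncol = ncell, byrow = TRUE)
            cts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                         size = size),
                          nrow = length(genes),
                          dimnames = list(genes, sprintf("%s_c%04d", sample_id,
                                                         seq_len(ncell))))
            mats[[si]] <- methods::as(cts, "CsparseMatrix")
            metas[[si]] <- data.frame(sample = sample_id, condition = cond,
                                      stringsAsFactors = FALSE)[rep(1, ncell), ]
            truth_types <- c(truth_types,
                             stats::setNames(types, colnames(cts)))
            fr_rows[[si]] <- data.frame(
                sample = sample_id, condition = cond, cell_type = names(frac),
                n_cells = ncts, fraction = ncts / ncell,
                stringsAsFactors = FALSE)
        }
    }
    counts <- do.call(cbind, mats)
    meta <- do.call(rbind, metas)
    cohort <- TumorCohort(counts, meta$sample, meta$condition,
                          mito_genes = grep("^mt-", genes, value = TRUE))
    eff <- config@effectTable
    truth <- list(cell_types = truth_types,
                  sample_fractions = do.call(rbind, c(fr_rows,
                                                      make.row.names = FALSE)),
                  effects = eff,
                  coupled_pairs = eff[, intersect(colnames(eff),
                                                  c("condition", "cell_type",
                                                    "gene", "fold"))])
    list(cohort = cohort, truth = truth)
}

#' Generate a synthetic mutation table
#'
#' Emits the requested number of truncating and non-truncating records with
#' variant classifications drawn uniformly from the MAF taxonomy used by the
#' weighted TMB score (nonsense, frame-shift del/ins, splice site vs missense,
#' in-frame del/ins, nonstop).
#'
#' @param n_truncating,n_nontruncating record counts (>= 0).
#' @param seed integer seed.
#' @param sample sample identifier attached to every record.
#' @return data.frame(sample, gene, variant_classification).
#' @export
generateMutationTable <- function(n_truncating, n_nontruncating, seed = 1L,
                                  sample = "S1") {
    if (n_truncating < 0 || n_nontruncating < 0)
        stop("mutation counts must be nonnegative")
    trunc_classes <- c("Nonsense_Mutation", "Frame_Shift_Del",
                       "Frame_Shift_Ins", "Splice_Site")
    nontrunc_classes <- c("Missense_Mutation", "In_Frame_Del",
                          "In_Frame_Ins", "Nonstop_Mutation")
    set.seed(seed)
    n <- n_truncating + n_nontruncating
    cls <- c(if (n_truncating > 0)
                 sample(trunc_classes, n_truncating, replace = TRUE),
             if (n_nontruncating > 0)
                 sample(nontrunc_classes, n_nontruncating, replace = TRUE))
    data.frame(sample = rep(sample, n),
               gene = if (n > 0) sprintf("GENE%04d", sample.int(9999, n,
                                                                replace = TRUE))
                      else character(),
               variant_classification = if (n > 0) cls else character(),
               stringsAsFactors = FALSE)
}

#' Generate synthetic exponential tumor growth curves
#'
#' Mean volume follows \code{V0 * exp(rate * day)} per arm with multiplicative
#' lognormal noise per measurement; long/short diameters are back-computed
#' from volume assuming a spherical tumor (a = b), consistent with
#' \code{V = 0.5 a b^2}.
#'
#' @param n_per_arm animals per arm.
#' @param vehicle_rate,treated_rate exponential growth rates per day (>= 0).
#' @param noise_sd sd of lognormal measurement noise (0 = noise-free).
#' @param days strictly increasing measurement days (first day is day 0 of
#'   the TGI formula).
#' @param seed integer seed.
#' @param baseline_volume starting mean volume, mm^3.
#' @return data.frame(animal, arm, day, a_mm, b_mm, volume) with attribute
#'   \code{truth} = list(vehicle_rate, treated_rate, baseline_volume).
#' @export
generateGrowthCurves <- function(n_per_arm, vehicle_rate, treated_rate,
                                 noise_sd, days, seed = 1L,
                                 baseline_volume = 100) {
    if (length(days) == 0) stop("days must be nonempty")
    if (any(diff(days) <= 0)) stop("days must be strictly increasing")
    if (vehicle_rate < 0 || treated_rate < 0) stop("rates must be nonnegative")
    set.seed(seed)
    rows <- list()
    for (arm in c("vehicle", "treated")) {
        rate <- if (arm == "vehicle") vehicle_rate else treated_rate
        for (i in seq_len(n_per_arm)) {
            mu <- baseline_volume * exp(rate * (days - days[1]))
            noise <- if (noise_sd > 0) exp(stats::rnorm(length(days), 0, noise_sd))
                     else rep(1, length(days))
            v <- mu * noise
            a <- (2 * v)^(1 / 3)
            rows[[length(rows) + 1L]] <- data.frame(
                animal = sprintf("%s_%02d", arm, i), arm = arm, day = days,
                a_mm = a, b_mm = a, volume = v, stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, c(rows, make.row.names = FALSE))
    attr(out, "truth") <- list(vehicle_rate = vehicle_rate,
                               treated_rate = treated_rate,
                               baseline_volume = baseline_volume)
    out
}

#' Generate synthetic survival data
#'
#' Exponential event times: control arm hazard \code{baseline_hazard}, treated
#' arm \code{baseline_hazard * hazard_ratio}. Independent exponential
#' censoring with rate \code{censor_rate * baseline_hazard} (none when
#' \code{censor_rate = 0}).
#'
#' @param n_per_arm subjects per arm.
#' @param hazard_ratio treated/control hazard ratio (> 0).
#' @param censor_rate censoring intensity relative to the baseline hazard.
#' @param seed integer seed.
#' @param baseline_hazard events per unit time in the control arm.
#' @return data.frame(subject, group, time, event) with attribute
#'   \code{truth} = list(hazard_ratio, baseline_hazard).
#' @export
generateSurvival <- function(n_per_arm, hazard_ratio, censor_rate = 0,
                             seed = 1L, baseline_hazard = 0.1) {
    if (hazard_ratio <= 0) stop("hazard_ratio must be > 0")
    if (censor_rate < 0) stop("censor_rate must be >= 0")
    set.seed(seed)
    mk <- function(group, hazard) {
        t_event <- stats::rexp(n_per_arm, rate = hazard)
        t_cens <- if (censor_rate > 0)
            stats::rexp(n_per_arm, rate = censor_rate * baseline_hazard)
        else rep(Inf, n_per_arm)
        data.frame(subject = sprintf("%s_%02d", group, seq_len(n_per_arm)),
                   group = group,
                   time = pmin(t_event, t_cens),
                   event = as.integer(t_event <= t_cens),
                   stringsAsFactors = FALSE)
    }
    out <- rbind(mk("control", baseline_hazard),
                 mk("treated", baseline_hazard * hazard_ratio))
    attr(out, "truth") <- list(hazard_ratio = hazard_ratio,
                               baseline_hazard = baseline_hazard)
    out
}
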