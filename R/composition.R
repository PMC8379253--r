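#' Per-sample cell-type fractions
#'
#' Tallies cells per (sample, type) and divides by the sample's retained cell
#' count. Every cell contributes; \code{"unassigned"} is counted as its own
#' category, so fractions within a sample sum to 1 exactly.
#'
#' @param types per-cell cell-type labels (named by barcode) or a
#'   \linkS4class{CellTypeMap}.
#' @param sample per-cell sample ids, aligned with \code{types}.
#' @param condition optional per-cell condition labels.
#' @return data.frame(sample, condition, cell_type, n_cells, fraction).
#' @export
cellFractions <- function(types, sample, condition = NULL) {
    if (methods::is(types, "CellTypeMap")) types <- cellTypes(types)
    stopifnot(length(sample) == length(types))
    if (is.null(condition)) condition <- rep(NA_character_, length(types))
    samples <- unique(sample)
    empty <- samples[!samples %in% sample[!is.na(types)]]
    rows <- lapply(samples, function(s) {
        w <- sample == s
        if (!sum(w)) stop("sample has no cells: ", s)
        tab <- table(types[w])
        data.frame(sample = s,
                   condition = condition[w][1],
                   cell_type = names(tab),
                   n_cells = as.integer(tab),
                   fraction = as.numeric(tab) / sum(w),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Compare a cell type's fraction between two conditions
#'
#' Two-sided permutation test on per-sample fractions: the sample, not the
#' cell, is the unit of inference. Condition labels are permuted across
#' samples; when the number of distinct arrangements is at most
#' \code{max_exhaustive} the permutation distribution is enumerated exactly
#' (p = proportion of arrangements with |null difference| >= |observed|),
#' otherwise \code{n_perm} Monte-Carlo draws are used with the add-one
#' estimator p = (1 + #\{|null| >= |obs|\}) / (1 + n_perm).
#'
#' @param fractions table from \code{\link{cellFractions}}.
#' @param type cell type to compare.
#' @param condition_a,condition_b condition labels.
#' @param n_perm Monte-Carlo permutations (default 10000).
#' @param seed integer seed (Monte-Carlo path only).
#' @param max_exhaustive arrangement count below which enumeration is exact.
#' @return list(difference = mean_a - mean_b, p, method, n_a, n_b).
#' @export
compareFractions <- function(fractions, type, condition_a, condition_b,
                             n_perm = 10000L, seed = 1L,
                             max_exhaustive = 20000L) {
    if (!type %in% fractions$cell_type) stop("unknown cell type: ", type)
    # one fraction per sample; samples lacking the type contribute 0
    sub <- fractions[fractions$condition %in% c(condition_a, condition_b), ,
                     drop = FALSE]
    samp <- unique(sub[, c("sample", "condition")])
    fr <- vapply(samp$sample, function(s) {
        w <- sub$sample == s & sub$cell_type == type
        if (any(w)) sub$fraction[w][1] else 0
    }, numeric(1))
    is_a <- samp$condition == condition_a
    n_a <- sum(is_a); n_b <- sum(!is_a)
    if (n_a < 2 || n_b < 2)
        stop("need >= 2 samples per condition for a nondegenerate null")
    obs <- mean(fr[is_a]) - mean(fr[!is_a])
    n <- length(fr)
    n_arr <- choose(n, n_a)
    stat <- function(idx_a) mean(fr[idx_a]) - mean(fr[-idx_a])
    if (n_arr <= max_exhaustive) {
        combos <- utils::combn(n, n_a)
        null <- apply(combos, 2, stat)
        p <- mean(abs(null) >= abs(obs) - 1e-12)
        method <- "exhaustive"
    } else {
        set.seed(seed)
        null <- vapply(seq_len(n_perm), function(b)
            stat(sample.int(n, n_a)), numeric(1))
        p <- (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (1 + n_perm)
        method <- "monte_carlo"
    }
    list(difference = obs, p = p, method = method, n_a = n_a, n_b = n_b)
}
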