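#' Read a ligand-receptor pair table
#'
#' CSV with columns \code{pair_id, ligand, receptor}; pair ids must be unique
#' and gene names nonempty.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
readLRPairs <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    validateLRPairs(tab)
}

validateLRPairs <- function(tab) {
    need <- c("pair_id", "ligand", "receptor")
    if (!all(need %in% colnames(tab)))
        stop("LR pair table needs columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(tab$pair_id)) stop("pair ids must be unique")
    if (any(!nzchar(tab$ligand)) || any(!nzchar(tab$receptor)))
        stop("ligand and receptor must be nonempty")
    tab
}

# Mean expression of one gene over cells of one type; NA if gene absent.
typeMeanExpr <- function(expr, gene, cells) {
    if (!gene %in% rownames(expr)) return(NA_real_)
    mean(expr[gene, cells])
}

#' Score one ligand-receptor interaction between two cell types
#'
#' The score is the product of the mean normalized ligand expression over the
#' sender cells and the mean normalized receptor expression over the receiver
#' cells. When either type has fewer than \code{min_cells} cells the score is
#' flagged-missing (\code{NA}), never zero: absence of evidence is
#' distinguished from evidence of no expression.
#'
#' @param expr genes x cells normalized expression matrix.
#' @param types character vector of cell-type labels per cell (or a
#'   \linkS4class{CellTypeMap}).
#' @param ligand,receptor gene names of the pair.
#' @param sender,receiver cell-type labels.
#' @param min_cells minimum cells per type (default 10).
#' @return nonnegative numeric score, or \code{NA} when flagged-missing.
#' @export
interactionScore <- function(expr, types, ligand, receptor, sender, receiver,
                             min_cells = 10L) {
    if (methods::is(types, "CellTypeMap")) types <- cellTypes(types)
    stopifnot(length(types) == ncol(expr))
    s_cells <- which(types == sender)
    r_cells <- which(types == receiver)
    if (length(s_cells) < min_cells || length(r_cells) < min_cells)
        return(NA_real_)
    ml <- typeMeanExpr(expr, ligand, s_cells)
    mr <- typeMeanExpr(expr, receptor, r_cells)
    if (is.na(ml) || is.na(mr)) return(NA_real_)
    ml * mr
}

#' Permutation significance of an interaction score
#'
#' Builds the enrichment null by shuffling cell-type labels across cells
#' (within sample when \code{sample} is given), recomputing the mean-product
#' score \code{B} times, and reporting
#' \code{p = (1 + #\{null >= observed\}) / (1 + B)}. Deterministic given
#' \code{seed}.
#'
#' @inheritParams interactionScore
#' @param B number of permutations (>= 1; default 1000).
#' @param seed integer seed.
#' @param sample optional per-cell sample ids; labels are shuffled within
#'   sample to respect the cohort structure.
#' @return list(observed, p, B).
#' @export
permutationSignificance <- function(expr, types, ligand, receptor, sender,
                                    receiver, B = 1000L, seed = 1L,
                                    sample = NULL, min_cells = 10L) {
    if (B < 1) stop("B must be >= 1")
    if (methods::is(types, "CellTypeMap")) types <- cellTypes(types)
    obs <- interactionScore(expr, types, ligand, receptor, sender, receiver,
                            min_cells)
    if (is.na(obs)) stop("observed score is not computable (too few cells)")
    # only the two pair genes matter for the null
    lx <- as.numeric(expr[ligand, ])
    rx <- as.numeric(expr[receptor, ])
    is_s <- types == sender
    is_r <- types == receiver
    set.seed(seed)
    perm_idx <- function() {
        if (is.null(sample)) return(sample.int(length(types)))
        idx <- seq_along(types)
        for (s in unique(sample)) {
            w <- which(sample == s)
            idx[w] <- w[sample.int(length(w))]
        }
        idx
    }
    null <- vapply(seq_len(B), function(b) {
        idx <- perm_idx()
        mean(lx[idx[is_s]]) * mean(rx[idx[is_r]])
    }, numeric(1))
    p <- (1 + sum(null >= obs)) / (1 + B)
    list(observed = obs, p = p, B = as.integer(B))
}

# Fraction of cells of a type in which a gene is detected (> 0).
detectedFraction <- function(counts_or_expr, gene, cells) {
    if (!gene %in% rownames(counts_or_expr) || !length(cells)) return(0)
    mean(counts_or_expr[gene, cells] > 0)
}

#' Per-sample interaction scores for a pair table
#'
#' Computes \code{\link{interactionScore}} for every pair in every sample,
#' together with expressed flags (gene detected in at least
#' \code{min_expressed_frac} of the relevant type's cells in that sample).
#'
#' @param cohort a normalized \linkS4class{TumorCohort}.
#' @param types a \linkS4class{CellTypeMap} or per-cell type labels.
#' @param pairs LR pair table (pair_id, ligand, receptor).
#' @param sender,receiver cell-type labels.
#' @param min_cells minimum cells per type per sample.
#' @param min_expressed_frac detection fraction for the expressed gate
#'   (default 0.10).
#' @return data.frame(pair_id, ligand, receptor, sample, score,
#'   ligand_expressed, receptor_expressed).
#' @export
scoreInteractions <- function(cohort, types, pairs, sender, receiver,
                              min_cells = 10L, min_expressed_frac = 0.10) {
    validateLRPairs(pairs)
    if (methods::is(types, "CellTypeMap")) types <- cellTypes(types)
    expr <- assay(cohort, "logcounts")
    samples <- unique(sampleIds(cohort))
    rows <- lapply(samples, function(s) {
        in_s <- sampleIds(cohort) == s
        e <- expr[, in_s, drop = FALSE]
        ty <- types[in_s]
        s_cells <- which(ty == sender)
        r_cells <- which(ty == receiver)
        data.frame(
            pair_id = pairs$pair_id, ligand = pairs$ligand,
            receptor = pairs$receptor, sample = s,
            score = vapply(seq_len(nrow(pairs)), function(i)
                interactionScore(e, ty, pairs$ligand[i], pairs$receptor[i],
                                 sender, receiver, min_cells), numeric(1)),
            ligand_expressed = vapply(pairs$ligand, function(g)
                detectedFraction(e, g, s_cells) >= min_expressed_frac,
                logical(1)),
            receptor_expressed = vapply(pairs$receptor, function(g)
                detectedFraction(e, g, r_cells) >= min_expressed_frac,
                logical(1)),
            stringsAsFactors = FALSE, row.names = NULL)
    })
    do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Group means and conserved-interaction calls
#'
#' Averages each pair's per-sample scores within each group (model x
#' condition); flagged-missing samples are excluded from the mean, and a
#' group with no scoreable sample gets a flagged-missing mean. A pair is
#' conserved when, in every group, its permutation p-value is <= alpha and
#' both expressed flags hold.
#'
#' @param per_sample per-sample score table from
#'   \code{\link{scoreInteractions}}.
#' @param groups named character vector: sample -> group label.
#' @param group_p optional data.frame(pair_id, group, p) of per-group
#'   permutation p-values; when absent, significance is not required and
#'   conservation reduces to the expressed criterion.
#' @param alpha significance level (default 0.05).
#' @return list(per_group = data.frame(pair_id, group, mean_score, n_samples,
#'   p, q, ligand_expressed, receptor_expressed), conserved =
#'   data.frame(pair_id, significant_all_groups, expressed_all_groups,
#'   conserved)). q is the Benjamini-Hochberg adjustment of p across pairs
#'   within each group.
#' @export
conservedInteractions <- function(per_sample, groups, group_p = NULL,
                                  alpha = 0.05) {
    if (!all(unique(per_sample$sample) %in% names(groups)))
        stop("every sample must be mapped to exactly one group")
    per_sample$group <- unname(groups[per_sample$sample])
    grp_levels <- unique(unname(groups))
    pair_ids <- unique(per_sample$pair_id)
    rows <- list()
    for (g in grp_levels) {
        sub <- per_sample[per_sample$group == g, , drop = FALSE]
        for (pid in pair_ids) {
            ss <- sub[sub$pair_id == pid, , drop = FALSE]
            ok <- !is.na(ss$score)
            rows[[length(rows) + 1L]] <- data.frame(
                pair_id = pid, group = g,
                mean_score = if (any(ok)) mean(ss$score[ok]) else NA_real_,
                n_samples = sum(ok),
                ligand_expressed = all(ss$ligand_expressed[ok]) && any(ok),
                receptor_expressed = all(ss$receptor_expressed[ok]) && any(ok),
                stringsAsFactors = FALSE)
        }
    }
    per_group <- do.call(rbind, c(rows, make.row.names = FALSE))
    if (!is.null(group_p)) {
        per_group <- merge(per_group, group_p[, c("pair_id", "group", "p")],
                           by = c("pair_id", "group"), all.x = TRUE,
                           sort = FALSE)
    } else per_group$p <- NA_real_
    per_group$q <- NA_real_
    for (g in grp_levels) {
        w <- per_group$group == g
        per_group$q[w] <- stats::p.adjust(per_group$p[w], method = "BH")
    }
    sig_all <- vapply(pair_ids, function(pid) {
        pp <- per_group$p[per_group$pair_id == pid]
        all(!is.na(pp) & pp <= alpha)
    }, logical(1))
    expr_all <- vapply(pair_ids, function(pid) {
        w <- per_group$pair_id == pid
        all(per_group$ligand_expressed[w] & per_group$receptor_expressed[w] &
            per_group$n_samples[w] > 0)
    }, logical(1))
    conserved <- data.frame(
        pair_id = pair_ids,
        significant_all_groups = sig_all,
        expressed_all_groups = expr_all,
        conserved = (if (is.null(group_p)) TRUE else sig_all) & expr_all,
        stringsAsFactors = FALSE, row.names = NULL)
    list(per_group = per_group, conserved = conserved)
}

#' Rank interactions within a group
#'
#' Descending by group mean score; ties broken by smaller p, then pair id
#' lexicographically. Flagged-missing means sort last.
#'
#' @param per_group per-group table from \code{\link{conservedInteractions}}
#'   or \code{\link{groupSummary}}.
#' @param group group label to rank within.
#' @return the group's rows of \code{per_group}, ordered.
#' @export
rankInteractions <- function(per_group, group) {
    sub <- per_group[per_group$group == group, , drop = FALSE]
    if (!nrow(sub)) stop("unknown group: ", group)
    ms <- sub$mean_score
    ms[is.na(ms)] <- -Inf
    p <- if ("p" %in% colnames(sub)) sub$p else rep(NA_real_, nrow(sub))
    p[is.na(p)] <- Inf
    sub[order(-ms, p, sub$pair_id), , drop = FALSE]
}

#' Full ligand-receptor interaction analysis
#'
#' Scores every pair per sample, computes per-group permutation significance
#' on the pooled cells of each group (labels shuffled within sample), applies
#' Benjamini-Hochberg within each group, and calls conserved interactions.
#'
#' @inheritParams scoreInteractions
#' @param groups named character vector sample -> group label; defaults to
#'   the cohort's condition labels.
#' @param B permutations per group per pair (default 1000).
#' @param alpha significance level for conserved calls.
#' @param seed integer seed.
#' @return an \linkS4class{InteractionResults}.
#' @export
interactionAnalysis <- function(cohort, types, pairs, sender, receiver,
                                groups = NULL, B = 1000L, alpha = 0.05,
                                seed = 1L, min_cells = 10L,
                                min_expressed_frac = 0.10) {
    if (methods::is(types, "CellTypeMap")) types <- cellTypes(types)
    if (is.null(groups)) {
        cd <- unique(data.frame(sample = sampleIds(cohort),
                                condition = conditionLabels(cohort)))
        groups <- stats::setNames(cd$condition, cd$sample)
    }
    per_sample <- scoreInteractions(cohort, types, pairs, sender, receiver,
                                    min_cells, min_expressed_frac)
    expr <- assay(cohort, "logcounts")
    samp <- sampleIds(cohort)
    grp_of_cell <- unname(groups[samp])
    prows <- list()
    for (g in unique(unname(groups))) {
        in_g <- grp_of_cell == g
        e <- expr[, in_g, drop = FALSE]
        ty <- types[in_g]
        sm <- samp[in_g]
        for (i in seq_len(nrow(pairs))) {
            p <- tryCatch(
                permutationSignificance(e, ty, pairs$ligand[i],
                                        pairs$receptor[i], sender, receiver,
                                        B = B,
                                        seed = seed + i * 131L,
                                        sample = sm, min_cells = min_cells)$p,
                error = function(err) NA_real_)
            prows[[length(prows) + 1L]] <- data.frame(
                pair_id = pairs$pair_id[i], group = g, p = p,
                stringsAsFactors = FALSE)
        }
    }
    group_p <- do.call(rbind, c(prows, make.row.names = FALSE))
    cons <- conservedInteractions(per_sample, groups, group_p, alpha)
    methods::new("InteractionResults", sender = sender, receiver = receiver,
                 perSample = per_sample, perGroup = cons$per_group,
                 conserved = cons$conserved, alpha = alpha)
}
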