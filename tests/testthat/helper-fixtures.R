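# Shared fixtures and independent mini-oracles used across test files.

# Tiny cohort from a dense count matrix (genes get names g1..gn unless set).
makeTinyCohort <- function(counts, sample = "s1", condition = "vehicle",
                           mito_genes = character()) {
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("g", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("c", seq_len(ncol(counts)))
    TumorCohort(counts, sample, condition, mito_genes = mito_genes)
}

# Adjusted Rand index, coded from the pair-counting definition (oracle for
# clustering comparisons; independent of any clustering library).
ari <- function(a, b) {
    tab <- table(a, b)
    sij <- sum(choose(tab, 2))
    si <- sum(choose(rowSums(tab), 2))
    sj <- sum(choose(colSums(tab), 2))
    n2 <- choose(sum(tab), 2)
    expected <- si * sj / n2
    (sij - expected) / ((si + sj) / 2 - expected)
}

# Two-condition simulation with one coupled ligand-receptor pair among decoys
# (the recovery scenario); returns config pieces shared by tests and the
# acceptance suite.
coupledScenario <- function(n_samples = 4L, n_cells = 1500L, n_decoys = 50L,
                            ligand_fold = 4, receptor_fold = 3, seed = 1L) {
    decoys <- data.frame(pair_id = sprintf("decoy%02d", seq_len(n_decoys)),
                         ligand = sprintf("DecL%02d", seq_len(n_decoys)),
                         receptor = sprintf("DecR%02d", seq_len(n_decoys)),
                         stringsAsFactors = FALSE)
    pairs <- rbind(data.frame(pair_id = "coupled", ligand = "Lig0",
                              receptor = "Rec0", stringsAsFactors = FALSE),
                   decoys)
    eff <- data.frame(condition = "treated",
                      cell_type = c("cancer", "CD8T"),
                      gene = c("Lig0", "Rec0"),
                      fold = c(ligand_fold, receptor_fold),
                      stringsAsFactors = FALSE)
    cfg <- simConfig(n_samples_per_condition = n_samples,
                     n_cells_per_sample = n_cells,
                     effect_table = eff, seed = seed)
    list(config = cfg, pairs = pairs)
}

# sample -> group map taken from a cohort's condition labels.
conditionGroups <- function(cohort) {
    m <- unique(data.frame(s = sampleIds(cohort), g = conditionLabels(cohort),
                           stringsAsFactors = FALSE))
    stats::setNames(m$g, m$s)
}
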