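test_that("interactionScore is the product of type means", {
    expr <- matrix(1, nrow = 2, ncol = 6,
                   dimnames = list(c("L", "R"), paste0("c", 1:6)))
    types <- c("S", "S", "S", "T", "T", "T")
    expect_equal(interactionScore(expr, types, "L", "R", "S", "T",
                                  min_cells = 1L), 1.0)
    expr2 <- expr; expr2["L", types == "S"] <- 0
    expect_equal(interactionScore(expr2, types, "L", "R", "S", "T",
                                  min_cells = 1L), 0.0)
    # hand computation: senders (0,1,2) receivers (3,1) -> 1.0 * 2.0
    expr3 <- matrix(0, nrow = 2, ncol = 5,
                    dimnames = list(c("L", "R"), paste0("c", 1:5)))
    expr3["L", 1:3] <- c(0, 1, 2)
    expr3["R", 4:5] <- c(3, 1)
    ty3 <- c("S", "S", "S", "T", "T")
    expect_equal(interactionScore(expr3, ty3, "L", "R", "S", "T",
                                  min_cells = 1L), 2.0)
    # too few cells: flagged-missing, not zero
    expect_true(is.na(interactionScore(expr3, ty3, "L", "R", "S", "T",
                                       min_cells = 4L)))
})

test_that("interactionScore invariances: cell order, unrelated genes, bilinearity", {
    set.seed(7)
    expr <- matrix(rexp(40), nrow = 4,
                   dimnames = list(c("L", "R", "x1", "x2"), paste0("c", 1:10)))
    types <- rep(c("S", "T"), 5)
    s0 <- interactionScore(expr, types, "L", "R", "S", "T", min_cells = 1L)
    perm <- sample(10)
    expect_equal(interactionScore(expr[, perm], types[perm], "L", "R",
                                  "S", "T", min_cells = 1L), s0)
    expr_noise <- expr; expr_noise["x1", ] <- 99
    expect_equal(interactionScore(expr_noise, types, "L", "R", "S", "T",
                                  min_cells = 1L), s0)
    expr_c <- expr; expr_c["L", ] <- 2.5 * expr_c["L", ]
    expect_equal(interactionScore(expr_c, types, "L", "R", "S", "T",
                                  min_cells = 1L), 2.5 * s0)
    expect_gte(s0, 0)
})

test_that("permutation p-value: exchangeability ceiling and formula floor", {
    expr <- matrix(1, nrow = 2, ncol = 20,
                   dimnames = list(c("L", "R"), paste0("c", 1:20)))
    types <- rep(c("S", "T"), each = 10)
    res <- permutationSignificance(expr, types, "L", "R", "S", "T",
                                   B = 99L, seed = 1L, min_cells = 1L)
    expect_equal(res$p, 1.0)   # constant expression: every null equals observed
    # perfectly aligned signal beats every permutation -> p = 1/(B+1)
    expr2 <- matrix(0, nrow = 2, ncol = 40,
                    dimnames = list(c("L", "R"), paste0("c", 1:40)))
    types2 <- rep(c("S", "T"), each = 20)
    expr2["L", types2 == "S"] <- 5
    expr2["R", types2 == "T"] <- 5
    res2 <- permutationSignificance(expr2, types2, "L", "R", "S", "T",
                                    B = 99L, seed = 1L, min_cells = 1L)
    expect_equal(res2$p, 1 / 100)
    expect_error(permutationSignificance(expr, types, "L", "R", "S", "T",
                                         B = 0L), "B must be")
    # determinism
    set.seed(99); e3 <- matrix(rexp(80), 2, 40,
                               dimnames = list(c("L", "R"), paste0("c", 1:40)))
    r1 <- permutationSignificance(e3, types2, "L", "R", "S", "T", B = 50L,
                                  seed = 3L, min_cells = 1L)
    r2 <- permutationSignificance(e3, types2, "L", "R", "S", "T", B = 50L,
                                  seed = 3L, min_cells = 1L)
    expect_identical(r1, r2)
})

test_that("conserved calls: group means, all-group significance, ordering", {
    per_sample <- data.frame(
        pair_id = "p1", ligand = "L", receptor = "R",
        sample = c("s1", "s2", "s3", "s4"),
        score = c(1.0, 3.0, 2.0, 4.0),
        ligand_expressed = TRUE, receptor_expressed = TRUE,
        stringsAsFactors = FALSE)
    groups <- c(s1 = "g1", s2 = "g1", s3 = "g2", s4 = "g2")
    gp <- data.frame(pair_id = "p1", group = c("g1", "g2"), p = c(0.01, 0.02))
    out <- conservedInteractions(per_sample, groups, gp, alpha = 0.05)
    expect_equal(out$per_group$mean_score[out$per_group$group == "g1"], 2.0)
    expect_true(out$conserved$conserved)
    # significant in only 3 of 4 groups -> not conserved
    ps4 <- do.call(rbind, lapply(1:4, function(i)
        transform(per_sample[1:1, ], sample = paste0("s", i))))
    g4 <- stats::setNames(paste0("g", 1:4), paste0("s", 1:4))
    gp4 <- data.frame(pair_id = "p1", group = paste0("g", 1:4),
                      p = c(0.01, 0.01, 0.01, 0.2))
    out4 <- conservedInteractions(ps4, g4, gp4, alpha = 0.05)
    expect_false(out4$conserved$conserved)
    expect_false(out4$conserved$significant_all_groups[1])
    # sample-order invariance
    shuf <- per_sample[c(3, 1, 4, 2), ]
    out_s <- conservedInteractions(shuf, groups, gp, alpha = 0.05)
    expect_equal(out_s$per_group[order(out_s$per_group$group), ],
                 out$per_group[order(out$per_group$group), ],
                 ignore_attr = TRUE)
    # a group with no scoreable sample is flagged-missing and not conserved
    ps_na <- per_sample; ps_na$score[3:4] <- NA
    out_na <- conservedInteractions(ps_na, groups, gp, alpha = 0.05)
    expect_true(is.na(out_na$per_group$mean_score[out_na$per_group$group == "g2"]))
    expect_false(out_na$conserved$conserved)
})

test_that("group means equal a brute-force group-by average on random tables", {
    set.seed(14)
    for (rep in 1:20) {
        n_pairs <- sample(2:6, 1); n_samp <- sample(4:8, 1)
        per_sample <- expand.grid(pair_id = paste0("p", seq_len(n_pairs)),
                                  sample = paste0("s", seq_len(n_samp)),
                                  stringsAsFactors = FALSE)
        per_sample$ligand <- "L"; per_sample$receptor <- "R"
        per_sample$score <- rexp(nrow(per_sample))
        per_sample$score[sample(nrow(per_sample), 2)] <- NA
        per_sample$ligand_expressed <- TRUE
        per_sample$receptor_expressed <- TRUE
        groups <- stats::setNames(sample(c("a", "b"), n_samp, replace = TRUE),
                                  paste0("s", seq_len(n_samp)))
        # force both groups present
        groups[1:2] <- c("a", "b")
        out <- conservedInteractions(per_sample, groups)$per_group
        for (i in seq_len(nrow(out))) {
            w <- per_sample$pair_id == out$pair_id[i] &
                 groups[per_sample$sample] == out$group[i]
            oracle <- mean(per_sample$score[w], na.rm = TRUE)
            if (is.nan(oracle)) expect_true(is.na(out$mean_score[i]))
            else expect_equal(out$mean_score[i], oracle)
        }
    }
})

test_that("rankInteractions sorts by mean, then p, then pair id", {
    pg <- data.frame(pair_id = c("a", "b", "c"), group = "g",
                     mean_score = c(5, 2, 9), p = 0.5)
    expect_identical(rankInteractions(pg, "g")$pair_id, c("c", "a", "b"))
    pg2 <- data.frame(pair_id = c("a", "b"), group = "g",
                      mean_score = c(3, 3), p = c(0.5, 0.01))
    expect_identical(rankInteractions(pg2, "g")$pair_id, c("b", "a"))
    pg3 <- data.frame(pair_id = c("b", "a"), group = "g",
                      mean_score = c(3, 3), p = c(0.5, 0.5))
    expect_identical(rankInteractions(pg3, "g")$pair_id, c("a", "b"))
    expect_error(rankInteractions(pg, "nope"), "unknown group")
})

test_that("a truly coupled pair is recovered among decoys", {
    sc <- coupledScenario(n_samples = 2L, n_cells = 800L, n_decoys = 20L,
                          seed = 31L)
    res <- generateCohort(sc$config, extra_genes = c(sc$pairs$ligand,
                                                     sc$pairs$receptor))
    co <- normalizeLog(res$cohort)
    tt <- res$truth$cell_types[colnames(co)]   # oracle typing
    ps <- scoreInteractions(co, tt, sc$pairs, "cancer", "CD8T")
    out <- conservedInteractions(ps, conditionGroups(co))
    rk <- rankInteractions(out$per_group, "treated")
    expect_lte(which(rk$pair_id == "coupled"), 3)
})
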