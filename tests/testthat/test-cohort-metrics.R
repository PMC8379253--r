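test_that("variant classification follows the truncating taxonomy", {
    expect_identical(classifyMutation("Nonsense_Mutation"), "truncating")
    expect_identical(classifyMutation("Frame_Shift_Del"), "truncating")
    expect_identical(classifyMutation("splice_site"), "truncating")
    expect_identical(classifyMutation("Missense_Mutation"), "non_truncating")
    expect_identical(classifyMutation("In_Frame_Ins"), "non_truncating")
    expect_identical(classifyMutation("Nonstop_Mutation"), "non_truncating")
    expect_identical(classifyMutation("Silent"), "excluded")
    expect_identical(classifyMutation("5'UTR"), "excluded")
    expect_identical(classifyMutation("MISSENSE_MUTATION"), "non_truncating")
    expect_identical(classifyMutation("weird", synonyms = c(weird = "truncating")),
                     "truncating")
})

test_that("tmbScore applies the 2.0/1.0 weighting and is additive", {
    tab <- data.frame(
        sample = "S1",
        variant_classification = c(rep("Nonsense_Mutation", 3),
                                   rep("Missense_Mutation", 4), "Silent"))
    expect_equal(tmbScore(tab, "S1"), 3 * 2.0 + 4 * 1.0)
    # excluded-only records score zero
    excl <- data.frame(sample = "S2", variant_classification = "Silent")
    expect_equal(tmbScore(excl, "S2"), 0.0)
    expect_error(tmbScore(tab, "nope"), "unknown sample")
    # 200 random records vs an independent per-record loop, plus additivity
    set.seed(8)
    classes <- c("Nonsense_Mutation", "Frame_Shift_Ins", "Splice_Site",
                 "Missense_Mutation", "In_Frame_Del", "Nonstop_Mutation",
                 "Silent", "3'UTR", "Intron")
    big <- data.frame(sample = "S1",
                      variant_classification = sample(classes, 200,
                                                      replace = TRUE))
    w <- c(Nonsense_Mutation = 2, Frame_Shift_Ins = 2, Splice_Site = 2,
           Missense_Mutation = 1, In_Frame_Del = 1, Nonstop_Mutation = 1,
           Silent = 0, "3'UTR" = 0, Intron = 0)
    oracle <- sum(vapply(big$variant_classification,
                         function(v) w[[v]], numeric(1)))
    expect_equal(tmbScore(big, "S1"), oracle)
    half <- seq_len(100)
    b1 <- big[half, ]; b2 <- big[-half, ]
    expect_equal(tmbScore(b1, "S1") + tmbScore(b2, "S1"), tmbScore(big, "S1"))
    expect_equal(tmbScore(big[sample(200), ], "S1"), tmbScore(big, "S1"))
})

test_that("median stratification with ties going high", {
    v <- c(a = 1, b = 2, c = 3, d = 4)
    st <- stratifyByExpression(v)
    expect_equal(st$median, 2.5)
    expect_identical(unname(st$groups[c("c", "d")]), c("high", "high"))
    expect_identical(unname(st$groups[c("a", "b")]), c("low", "low"))
    odd <- c(a = 1, b = 2, c = 9)
    expect_identical(unname(stratifyByExpression(odd)$groups["b"]), "high")
    # random vector vs sort-and-split oracle
    set.seed(12)
    r <- stats::setNames(rnorm(15), paste0("s", 1:15))
    st_r <- stratifyByExpression(r)
    expect_identical(unname(st_r$groups),
                     unname(ifelse(r >= stats::median(r), "high", "low")))
    expect_error(stratifyByExpression(rep(2, 5)), "degenerate")
    expect_error(stratifyByExpression(c(a = 1)), ">= 2 samples")
})

test_that("Kaplan-Meier estimate matches hand product-limit computation", {
    # worked 3-subject example: event at 1, censored at 2, event at 3
    tab <- data.frame(subject = 1:3, group = "g",
                      time = c(1, 2, 3), event = c(1, 0, 1))
    km <- kmEstimate(tab, "g")
    # hand computation: S(1) = 1 - 1/3 = 2/3; at t = 3 the risk set is the
    # single remaining subject, so S(3) = 2/3 * (1 - 1/1) = 0
    expect_equal(km$fun(0), 1)
    expect_equal(km$fun(1), 2 / 3)
    expect_equal(km$fun(2.5), 2 / 3)
    expect_equal(km$fun(3), 0)
    expect_true(all(diff(km$surv) <= 1e-12))        # nonincreasing
    # no censoring: reduces to 1 - ECDF of event times
    set.seed(3)
    t2 <- data.frame(subject = 1:30, group = "g", time = rexp(30), event = 1)
    km2 <- kmEstimate(t2, "g")
    ecdf2 <- stats::ecdf(t2$time)
    for (q in c(0.2, 0.5, 1, 2))
        expect_equal(km2$fun(q), 1 - ecdf2(q))
    # all censored: S identically 1
    t3 <- data.frame(subject = 1:5, group = "g", time = 1:5, event = 0)
    expect_true(all(kmEstimate(t3, "g")$surv == 1))
    # censoring the subject with the largest time leaves earlier values intact
    t4 <- t2
    t4$event[which.max(t4$time)] <- 0
    km4 <- kmEstimate(t4, "g")
    expect_equal(km4$fun(1), km2$fun(1))
    expect_equal(km4$fun(stats::median(t2$time)), km2$fun(stats::median(t2$time)))
    expect_error(kmEstimate(data.frame(subject = 1, group = "g", time = -1,
                                       event = 1), "g"), "negative")
    expect_error(kmEstimate(tab, "absent"), "empty")
})

# Independent log-rank oracle: explicit risk-set tabulation of the
# observed - expected statistic with the hypergeometric variance.
logrankOracle <- function(time, event, grp) {
    tms <- sort(unique(time[event == 1]))
    O <- 0; E <- 0; V <- 0
    for (t in tms) {
        at_risk <- time >= t
        n <- sum(at_risk); n1 <- sum(at_risk & grp == 1)
        d <- sum(time == t & event == 1)
        d1 <- sum(time == t & event == 1 & grp == 1)
        O <- O + d1
        E <- E + d * n1 / n
        if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (O - E)^2 / V
}

test_that("log-rank test: symmetry, degenerate cases, hand tabulation", {
    tab <- data.frame(subject = 1:6, group = rep(c("a", "b"), each = 3),
                      time = c(1, 2, 3, 1, 2, 3), event = 1)
    res <- logrankTest(tab, "a", "b")
    expect_equal(res$chisq, 0)
    expect_equal(res$p, 1)
    # toy 6-subject table vs the risk-set oracle
    tab2 <- data.frame(subject = 1:6, group = rep(c("a", "b"), each = 3),
                       time = c(1, 4, 6, 2, 3, 5), event = c(1, 1, 0, 1, 1, 1))
    res2 <- logrankTest(tab2, "a", "b")
    oracle <- logrankOracle(tab2$time, tab2$event, as.integer(tab2$group == "b"))
    expect_equal(res2$chisq, oracle, tolerance = 1e-8)
    # label-swap invariance
    res2r <- logrankTest(tab2, "b", "a")
    expect_equal(res2r$chisq, res2$chisq)
    expect_error(logrankTest(tab2[tab2$group == "a", ], "a", "b"), "nonempty")
    zero <- transform(tab2, event = 0)
    expect_error(logrankTest(zero, "a", "b"), "at least one event")
})

test_that("growth curves convert to endpoint survival records", {
    days <- c(0, 5, 10, 15)
    gc <- generateGrowthCurves(3, 0.25, 0.0, 0, days, seed = 2L,
                               baseline_volume = 100)
    # vehicle: 100 * exp(0.25 d) crosses 2000 between day 10 (1218) and 15 (4289)
    sv <- survivalFromGrowth(gc, endpoint_volume = 2000)
    veh <- sv[sv$group == "vehicle", ]
    expect_true(all(veh$event == 1))
    expect_true(all(veh$time == 15))
    tre <- sv[sv$group == "treated", ]
    expect_true(all(tre$event == 0))
    expect_true(all(tre$time == 15))
})
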