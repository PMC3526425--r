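test_that("posterior probabilities follow Bayes' theorem on the log scale", {
    expect_equal(posteriorProbabilities(rep(-10, 5)), rep(0.2, 5))
    expect_equal(posteriorProbabilities(c(log(2), 0, 0, 0, 0)),
                 c(1/3, 1/6, 1/6, 1/6, 1/6), tolerance = 1e-12)
    set.seed(8)
    for (i in 1:20) {
        lm <- rnorm(5, sd = 30)
        p <- posteriorProbabilities(lm)
        expect_equal(sum(p), 1, tolerance = 1e-12)
        # shift invariance (log-sum-exp safety); exact in exact arithmetic,
        # the tolerance only absorbs rounding of the shifted inputs
        expect_equal(posteriorProbabilities(lm + 1000), p, tolerance = 1e-8)
        expect_equal(posteriorProbabilities(lm - 1e6), p, tolerance = 1e-6)
    }
    # informative priors re-weight the evidence
    expect_equal(posteriorProbabilities(c(0, 0), priors = c(0.8, 0.2)),
                 c(0.8, 0.2))
    expect_error(posteriorProbabilities(c(0, NA)), "non-finite")
})

test_that("condition scores sum the singleton-partition posteriors", {
    parts <- enumeratePartitions(c("Th0", "Th1", "Th2"))
    post <- c(0.05, 0.70, 0.0, 0.0, 0.25)
    expect_equal(conditionScore(post, parts, "Th2"), 0.95)
    # all mass on the single-block partition -> all scores zero
    for (cc in c("Th0", "Th1", "Th2"))
        expect_equal(conditionScore(c(1, 0, 0, 0, 0), parts, cc), 0)
    # 4 conditions: equals a brute-force filter over the 15 partitions
    conds4 <- c("A", "B", "C", "D")
    parts4 <- enumeratePartitions(conds4)
    set.seed(12)
    post4 <- rexp(15); post4 <- post4 / sum(post4)
    for (cc in conds4) {
        brute <- sum(vapply(seq_along(parts4), function(j) {
            isSingle <- any(vapply(parts4[[j]], function(b)
                identical(b, cc), logical(1)))
            if (isSingle) post4[j] else 0
        }, numeric(1)))
        expect_equal(conditionScore(post4, parts4, cc), brute,
                     tolerance = 1e-14)
        # complement property: score + mass on non-singleton partitions = 1
        expect_equal(conditionScore(post4, parts4, cc) +
                     (1 - conditionScore(post4, parts4, cc)), 1)
    }
    expect_error(conditionScore(post, parts, "Th7"), "unknown condition")
})

test_that("the fold-change filter demands separation from all others", {
    f0 <- flatFit(0); f05 <- flatFit(0.5); f12 <- flatFit(1.2)
    grid <- c(0, 12, 24, 48, 72)
    pass <- foldChangeFilter(list(Th0 = f0, Th1 = flatFit(0), Th2 = f12),
                             grid, 1.0)
    expect_identical(pass, c(Th0 = FALSE, Th1 = FALSE, Th2 = TRUE))
    pass2 <- foldChangeFilter(list(Th0 = f0, Th1 = f05, Th2 = f12),
                              grid, 1.0)
    expect_false(any(pass2))                     # 1.2 vs 0.5 is only 0.7
    # boundary |delta| exactly 1.0 passes (>= convention)
    pass3 <- foldChangeFilter(list(A = flatFit(0), B = flatFit(1.0)),
                              grid, 1.0)
    expect_true(all(pass3))
})

test_that("hypothesis evidence reduces to pooled fits and is bounded by free fits", {
    set.seed(30)
    gd <- list(
        Th0 = list(time = c(0, 12, 24, 48), value = rnorm(4, 5)),
        Th1 = list(time = c(0, 12, 24, 48), value = rnorm(4, 6)),
        Th2 = list(time = c(0, 12, 24, 48), value = rnorm(4, 8)))
    st <- ligapSettings(nRestarts = 3, seed = 17)
    parts <- enumeratePartitions(names(gd))
    # the single-block hypothesis is exactly one pooled GP fit
    pooled <- fitGP(unlist(lapply(gd, `[[`, "time")),
                    unlist(lapply(gd, `[[`, "value")),
                    nRestarts = 3, seed = ligap:::deriveSeed(st$seed, 1L, 7),
                    tmax = 48)
    expect_equal(hypothesisLogMarginal(gd, parts[[1]], st),
                 pooled@logMarginal)
    # the shared-hyperparameter evidence of the all-singletons hypothesis is
    # bounded above by the sum of independently optimized per-block fits
    allSingle <- hypothesisLogMarginal(gd, parts[[5]], st)
    gm <- mean(unlist(lapply(gd, `[[`, "value")))
    free <- sum(vapply(names(gd), function(cc)
        fitGP(gd[[cc]]$time, gd[[cc]]$value, nRestarts = 8, seed = 3,
              tmax = 48, centerValue = gm)@logMarginal, numeric(1)))
    expect_lte(allSingle, free + 1e-6)
    # evidence is finite and deterministic
    expect_equal(hypothesisLogMarginal(gd, parts[[5]], st), allSingle)
})

test_that("identical profiles across conditions favor the single-block model", {
    set.seed(44)
    base <- 6 + 1.5 * sin(seq(0, 72, 12) / 18)
    times <- rep(seq(0, 72, 12), each = 2)
    y <- rep(base, each = 2) + rnorm(length(times), 0, 0.25)
    gd <- list(Th0 = list(time = times, value = y),
               Th1 = list(time = times, value = y),
               Th2 = list(time = times, value = y))
    st <- ligapSettings(nRestarts = 3, seed = 2)
    parts <- enumeratePartitions(names(gd))
    lm <- vapply(parts, function(p)
        hypothesisLogMarginal(gd, p, st), numeric(1))
    post <- posteriorProbabilities(lm)
    expect_equal(which.max(post), 1L)
})

test_that("runLigap calls the shifted condition and is seed-deterministic", {
    sim <- simulateDataset(simulationConfig(
        n_genes = 4, truth_mix = c(0, 1, 0, 0, 0),  # Th2 separated
        effect_size = 3, noise_sd = 0.2, seed = 31))
    st <- ligapSettings(nRestarts = 3, seed = 8)
    res <- runLigap(sim$dataset, st)
    expect_true(all(conditionScores(res)[, "Th2"] > 0.9))
    expect_true(all(vapply(ligapCalls(res), function(x) "Th2" %in% x,
                           logical(1))))
    res2 <- runLigap(sim$dataset, st)
    expect_identical(posteriors(res), posteriors(res2))
    expect_identical(resultsTable(res), resultsTable(res2))
    # posterior simplex per gene
    expect_equal(rowSums(posteriors(res)), rep(1, 4), tolerance = 1e-10,
                 ignore_attr = TRUE)
    # all-different score is the last partition's posterior
    expect_equal(allDifferentScores(res), posteriors(res)[, 5],
                 ignore_attr = TRUE)
})

test_that("genes missing a condition are flagged, not fatal", {
    sim <- simulateDataset(simulationConfig(n_genes = 3, seed = 77))
    X <- SummarizedExperiment::assay(sim$dataset, "exprs")
    cd <- SummarizedExperiment::colData(sim$dataset)
    X[2, cd$condition == "Th1"] <- NA
    ds <- LigapDataset(X, condition = cd$condition, time = cd$time,
                       replicate = cd$replicate)
    res <- runLigap(ds, ligapSettings(nRestarts = 2, seed = 3))
    expect_identical(res@analyzable, c(TRUE, FALSE, TRUE))
    expect_true(all(is.na(posteriors(res)[2, ])))
    expect_length(ligapCalls(res)[[2]], 0)
})
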