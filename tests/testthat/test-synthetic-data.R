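test_that("cohort generator matches the requested ideology histogram exactly", {
    counts <- c(24L, 52L, 49L, 36L, 9L, 4L)
    co <- generateCohort(174, counts, seed = 3)
    expect_identical(tabulate(ideology(co), 6L), counts)
    expect_identical(anyDuplicated(subjectIds(co)), 0L)
    # deterministic under the seed, different under another
    co2 <- generateCohort(174, counts, seed = 3)
    co3 <- generateCohort(174, counts, seed = 4)
    expect_identical(cohortData(co), cohortData(co2))
    expect_false(identical(cohortData(co), cohortData(co3)))
    expect_error(generateCohort(100, counts), "sum to n")
    expect_error(generateCohort(174, counts,
                                c(mother_conservatism = 1.2)), "in \\(-1, 1\\)")
})

test_that("latent-Gaussian copula hits covariate correlation targets", {
    counts <- c(700L, 1500L, 1400L, 1000L, 260L, 140L)
    co <- generateCohort(5000, counts,
                         c(mother_conservatism = 0.417, religiosity = 0),
                         seed = 1)
    d <- cohortData(co)
    r <- cor(d$mother_conservatism, d$conservatism)
    expect_gte(r, 0.367)
    expect_lte(r, 0.467)
    # target-zero covariate is independent
    expect_lt(abs(cor(d$religiosity, d$conservatism)), 0.05)
    # all reference targets within +-0.05 at large n
    co2 <- generateCohort(5000, counts, seed = 2)
    d2 <- cohortData(co2)
    targets <- referenceCovariateTargets()
    for (v in names(targets))
        expect_lt(abs(cor(d2[[v]], d2$conservatism) - targets[[v]]), 0.05,
                  label = paste("covariate", v))
})

test_that("BOLD generator plants edge-ideology signal and flags missing ROIs", {
    co <- tinyCohort(50, seed = 7)
    # null world: mean off-diagonal FC near zero
    ser0 <- generateBoldTimeSeries(co, plantedTruth(seed = 7), nRois = 12,
                                   nTimepoints = 120, tasks = "task1")
    ds0 <- assembleDataset(ser0)
    offdiag <- sapply(subjectIds(ds0), function(s) {
        E <- fcValues(getFC(ds0, s, "task1")); mean(E[upper.tri(E)])
    })
    expect_lt(abs(mean(offdiag)), 0.03)

    # missing ROI column flagged in every series
    serM <- generateBoldTimeSeries(co, plantedTruth(seed = 1), nRois = 12,
                                   nTimepoints = 60, tasks = "task1",
                                   missingRoi = 5)
    expect_true(all(vapply(serM, function(s)
        identical(s@missingRois, 5L), logical(1))))

    # one planted edge spanning correlation 0.1 -> 0.7 across ideology 1..6
    counts <- round(referenceIdeologyCounts() * 200 / 174)
    counts[2] <- counts[2] + (200 - sum(counts))
    co2 <- generateCohort(200, counts, seed = 11)
    y <- ideology(co2); z <- (y - mean(y)) / sd(y)
    zr <- (c(1, 6) - mean(y)) / sd(y)
    eff <- (0.7 - 0.1) / (zr[2] - zr[1])
    base <- 0.1 - eff * zr[1]
    tr <- plantedTruth(data.frame(task = "task1", roi_i = 2L, roi_j = 9L,
                                  effect = eff), baseCorr = base, seed = 11)
    ser <- generateBoldTimeSeries(co2, tr, nRois = 12, nTimepoints = 150,
                                  tasks = "task1")
    ds <- assembleDataset(ser)
    edge <- sapply(subjectIds(ds), function(s)
        fcValues(getFC(ds, s, "task1"))[2, 9])
    expect_gt(cor(edge, ideology(co2)), 0.5)

    # out-of-range correlations are rejected
    trBad <- plantedTruth(data.frame(task = "task1", roi_i = 1L, roi_j = 2L,
                                     effect = 0.5), baseCorr = 0.9, seed = 1)
    expect_error(generateBoldTimeSeries(co2, trBad, nRois = 5,
                                        nTimepoints = 60, tasks = "task1"),
                 "outside \\(-1, 1\\)")
})

test_that("simulated score matrices realize per-task correlation targets", {
    counts <- c(280L, 600L, 560L, 410L, 100L, 50L)
    co <- generateCohort(2000, counts, seed = 7)
    sig <- c(0.5, 0.2, 0, -0.3)
    sm <- generateScoreMatrix(co, sig, seed = 7)
    r <- cor(scoreValues(sm), ideology(co))
    expect_true(all(abs(r - sig) < 0.05))
    # limit case: near-unit target reproduces standardized ideology
    sm2 <- generateScoreMatrix(co, 0.9999, seed = 1)
    expect_gt(cor(scoreValues(sm2)[, 1], ideology(co)), 0.999)
    expect_error(generateScoreMatrix(co, 1.5), "in \\(-1, 1\\)")
})

test_that("planted-truth container enforces edge conventions", {
    expect_error(plantedTruth(data.frame(task = "t", roi_i = 5L, roi_j = 2L,
                                         effect = 0.1)), "roi_i < roi_j")
    expect_error(plantedTruth(data.frame(task = c("t", "t"),
                                         roi_i = c(1L, 1L),
                                         roi_j = c(2L, 2L),
                                         effect = c(0.1, 0.2))), "once")
})
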