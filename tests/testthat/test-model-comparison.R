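test_that("dichotomization groups the conservative side as positive", {
    expect_identical(dichotomize(c(1, 2, 3)), c(0L, 0L, 0L))
    expect_identical(dichotomize(c(4, 5, 6)), c(1L, 1L, 1L))
    co <- generateCohort(174, c(24L, 52L, 49L, 36L, 9L, 4L), seed = 1)
    lab <- dichotomize(co)
    expect_identical(sum(lab == 1L), 49L)
    expect_identical(sum(lab == 0L), 125L)
    expect_error(dichotomize(c(0, 7)), "outside")
})

test_that("logistic fitting covers separation, prevalence and ML recovery", {
    set.seed(20)
    # perfectly separating predictor: training AUC 1, separation flagged
    lab <- rep(c(0L, 1L), each = 20)
    feats <- data.frame(x = lab * 2 - 1 + 0.01 * rnorm(40), z = rnorm(40))
    fit <- fitLogistic(feats, lab, "x")
    expect_true(fit$separation)
    expect_equal(aucScore(predict(fit, feats), lab), 1)

    # ML logistic with intercept: mean fitted probability = class prevalence
    labU <- rep(c(0L, 1L), c(30, 10))
    featsU <- data.frame(z = rnorm(40))
    expect_error(fitLogistic(featsU, rep(0L, 40), "z"), "single class")
    fitU <- fitLogistic(featsU, labU, "z")
    expect_equal(mean(predict(fitU, featsU)), 0.25, tolerance = 1e-6)

    # ML consistency: beta = (1, -0.5) recovered within +-0.1 at n = 5000
    n <- 5000
    X <- data.frame(a = rnorm(n), b = rnorm(n))
    p <- plogis(0.2 + X$a - 0.5 * X$b)
    y <- rbinom(n, 1, p)
    fitML <- fitLogistic(X, y)
    expect_lt(abs(coef(fitML)["a"] - 1), 0.1)
    expect_lt(abs(coef(fitML)["b"] + 0.5), 0.1)

    # duplicated predictor leaves fitted probabilities unchanged
    X2 <- X; X2$a2 <- X2$a
    p1 <- predict(fitLogistic(X, y), X)
    p2 <- suppressWarnings(predict(fitLogistic(X2, y), X2))
    expect_lt(max(abs(p1 - p2)), 1e-6)
})

test_that("Monte Carlo CV pairs splits across models and hits chance on null", {
    set.seed(21)
    n <- 120
    lab <- rbinom(n, 1, 0.45)
    while (length(unique(lab)) < 2) lab <- rbinom(n, 1, 0.45)
    feats <- data.frame(sig = lab + 0.05 * rnorm(n), noise = rnorm(n))
    models <- list(modelSpec("sig", "sig"), modelSpec("noise", "noise"))
    res <- monteCarloCV(models, feats, lab, nSamples = 200, seed = 3)
    summ <- res@summary
    expect_equal(summ$mean_auc[summ$model == "sig"], 1, tolerance = 1e-6)
    aucN <- summ$mean_auc[summ$model == "noise"]
    expect_gte(aucN, 0.45); expect_lte(aucN, 0.55)
    expect_true(all(summ$ci_low <= summ$mean_auc &
                    summ$mean_auc <= summ$ci_high))
    expect_true(all(res@auc >= 0 & res@auc <= 1))

    # determinism: identical seed, identical AUC draws (paired splits)
    res2 <- monteCarloCV(models, feats, lab, nSamples = 50, seed = 9)
    res3 <- monteCarloCV(models, feats, lab, nSamples = 50, seed = 9)
    expect_identical(res2@auc, res3@auc)

    # nested model adding pure noise stays within 1 SD of the base model
    feats2 <- data.frame(x = lab + rnorm(n), junk = rnorm(n))
    nested <- list(modelSpec("base", "x"), modelSpec("base+junk",
                                                     c("x", "junk")))
    resN <- monteCarloCV(nested, feats2, lab, nSamples = 200, seed = 5)
    sN <- resN@summary
    expect_lt(abs(sN$mean_auc[1] - sN$mean_auc[2]), sN$sd_auc[1])
})

test_that("benchmark classification follows the CI disjointness rule", {
    set.seed(22)
    n <- 150
    lab <- rep(c(0L, 1L), length.out = n)
    feats <- data.frame(
        mother_conservatism = lab + rnorm(n, 0, 2),
        father_conservatism = lab + rnorm(n, 0, 2),
        perfect = lab * 3 + 0.01 * rnorm(n),
        same_m = NA_real_, same_f = NA_real_)
    feats$same_m <- feats$mother_conservatism
    feats$same_f <- feats$father_conservatism
    models <- list(parentConservatismSpec(),
                   modelSpec("Clone", c("same_m", "same_f")),
                   modelSpec("Oracle", "perfect"))
    res <- monteCarloCV(models, feats, lab, nSamples = 150, seed = 7)
    tab <- compareToBenchmark(res)
    expect_identical(tab$vs_benchmark[tab$model == "Parent Conservatism"],
                     "indistinguishable")
    expect_identical(tab$vs_benchmark[tab$model == "Clone"],
                     "indistinguishable")
    expect_identical(tab$vs_benchmark[tab$model == "Oracle"], "above")
    expect_error(compareToBenchmark(res, "absent"), "not in result")
})

test_that("null synthetic scores give chance-level FC-model AUC", {
    co <- tinyCohort(174, seed = 23)
    sm <- generateScoreMatrix(co, rep(0, 9), seed = 23)
    feats <- assembleFeatures(sm, co)
    lab <- dichotomize(co)
    res <- monteCarloCV(list(fcModelSpec(taskIds(sm))), feats, lab,
                        nSamples = 200, seed = 23)
    auc <- res@summary$mean_auc
    expect_gte(auc, 0.45); expect_lte(auc, 0.55)
})
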