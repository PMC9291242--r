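#' Dichotomize 6-point ideology into conservative vs liberal
#'
#' Levels 4-6 (conservative, somewhat conservative, very conservative)
#' map to 1; levels 1-3 (very liberal, somewhat liberal, liberal) to 0.
#'
#' @param cohort a [Cohort-class] or an integer vector of 1-6 levels.
#' @return Integer 0/1 labels (1 = conservative).
#' @examples
#' dichotomize(c(1, 3, 4, 6))  # 0 0 1 1
#' @export
dichotomize <- function(cohort) {
    y <- if (is(cohort, "Cohort")) ideology(cohort) else cohort
    if (any(y < 1L | y > 6L)) stop("ideology outside 1..6")
    as.integer(y >= 4L)
}

#' Build the joint feature table of task scores and survey covariates
#'
#' One row per subject: the nine out-of-fold task score columns (named by
#' task) followed by the survey covariates (everything in the cohort
#' except the identifier and the outcome).
#'
#' @param scores an [IdeologyScoreMatrix-class].
#' @param cohort a [Cohort-class].
#' @return data.frame of predictors aligned to the score matrix rows.
#' @export
assembleFeatures <- function(scores, cohort) {
    S <- scoreValues(scores)
    d <- cohortData(cohort)
    ord <- match(rownames(S), d$subject_id)
    if (anyNA(ord)) stop("score subjects missing from cohort")
    cov <- d[ord, setdiff(names(d), c("subject_id", "conservatism")),
             drop = FALSE]
    out <- cbind(as.data.frame(S), cov)
    rownames(out) <- rownames(S)
    out
}

#' Specify a logistic model by name and predictor set
#'
#' @param name model label (used in comparison tables).
#' @param predictors character vector of feature-table column names.
#' @return A classed list.
#' @seealso [surveyModelSpec()], [parentConservatismSpec()]
#' @export
modelSpec <- function(name, predictors) {
    if (!length(predictors)) stop("predictor set must be non-empty")
    structure(list(name = name, predictors = unique(predictors)),
              class = "ModelSpec")
}

#' Preset model specifications
#'
#' `parentConservatismSpec()` is the benchmark containing mother's and
#' father's self-reported conservatism — the field-standard strongest
#' survey predictor of own ideology. `surveyModelSpec()` bundles the
#' survey covariates (age, education, income, parents' income, origin and
#' current city conservatism and parents' conservatism; sex optional,
#' since descriptions of the survey set differ on whether it is
#' included). `fcModelSpec()` uses the task score columns, and
#' `combinedModelSpec()` their union with the survey set.
#'
#' @param tasks task names for the FC-score predictors.
#' @param includeSex include the `male` indicator in the survey set.
#' @return A [modelSpec()].
#' @name modelPresets
NULL

#' @rdname modelPresets
#' @export
parentConservatismSpec <- function() {
    modelSpec("Parent Conservatism",
              c("mother_conservatism", "father_conservatism"))
}

#' @rdname modelPresets
#' @export
surveyModelSpec <- function(includeSex = FALSE) {
    pred <- c("age", "education", "income", "parent_income",
              "origin_city_conservatism", "current_city_conservatism",
              "mother_conservatism", "father_conservatism")
    if (includeSex) pred <- c("male", pred)
    modelSpec("Survey", pred)
}

#' @rdname modelPresets
#' @export
fcModelSpec <- function(tasks) modelSpec("FC scores", tasks)

#' @rdname modelPresets
#' @export
combinedModelSpec <- function(tasks, includeSex = FALSE) {
    modelSpec("Survey + FC",
              c(surveyModelSpec(includeSex)$predictors, tasks))
}

#' Fit a logistic regression with a regularized separation fallback
#'
#' Maximum-likelihood logistic fit of binary labels on the given
#' predictors. Complete or quasi-complete separation (detected from
#' divergent coefficients or degenerate fitted probabilities) is flagged
#' and the fit falls back to a lightly ridge-penalized logistic model so
#' predictions remain usable.
#'
#' @param features data.frame of predictors.
#' @param labels binary 0/1 vector.
#' @param predictors columns of `features` to use (default: all).
#' @return Object of class `ideoconnLogit` with a `predict` method
#'   returning probabilities.
#' @export
fitLogistic <- function(features, labels, predictors = names(features)) {
    if (length(unique(labels)) < 2L) stop("labels contain a single class")
    X <- features[, predictors, drop = FALSE]
    if (anyNA(X)) stop("missing values in features")
    df <- data.frame(.y = labels, X, check.names = FALSE)
    fit <- suppressWarnings(
        stats::glm(.y ~ ., data = df, family = stats::binomial()))
    sep <- !fit$converged || any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)
    if (sep) {
        Xm <- as.matrix(X)
        if (ncol(Xm) == 1L) Xm <- cbind(Xm, .pad = 0)
        rfit <- glmnet::glmnet(Xm, labels, family = "binomial", alpha = 0,
                               lambda = 1e-2)
        obj <- list(type = "ridge", fit = rfit, predictors = predictors,
                    separation = TRUE)
    } else {
        obj <- list(type = "glm", fit = fit, predictors = predictors,
                    separation = FALSE)
    }
    class(obj) <- "ideoconnLogit"
    obj
}

#' @export
predict.ideoconnLogit <- function(object, newdata, ...) {
    X <- newdata[, object$predictors, drop = FALSE]
    if (object$type == "glm") {
        unname(stats::predict(object$fit, newdata = X, type = "response"))
    } else {
        Xm <- as.matrix(X)
        if (ncol(Xm) == 1L) Xm <- cbind(Xm, .pad = 0)
        drop(stats::predict(object$fit, newx = Xm, type = "response"))
    }
}

#' @export
coef.ideoconnLogit <- function(object, ...) {
    if (object$type == "glm") stats::coef(object$fit)
    else drop(as.matrix(stats::coef(object$fit)))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of probabilities against binary labels.
#'
#' @param prob predicted probabilities.
#' @param labels binary 0/1 vector containing both classes.
#' @return Scalar AUC in [0, 1].
#' @export
aucScore <- function(prob, labels) {
    pos <- prob[labels == 1]
    neg <- prob[labels == 0]
    if (!length(pos) || !length(neg)) stop("AUC needs both classes")
    r <- rank(c(pos, neg))
    (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
        (length(pos) * length(neg))
}

#' Monte Carlo cross-validated comparison of logistic models
#'
#' For each of `nSamples` draws, a test fraction is drawn uniformly from
#' `testFractionRange`, a random test set of that fraction is held out,
#' every model is fitted on the remaining subjects and evaluated on the
#' identical test set (paired splits), and test AUC and accuracy
#' (probability threshold 0.5) are recorded. Splits leaving a single
#' class in train or test are resampled, up to 100 retries.
#'
#' @param models list of [modelSpec()] objects.
#' @param features data.frame from [assembleFeatures()].
#' @param labels binary 0/1 vector.
#' @param nSamples number of Monte Carlo samples (default 1000).
#' @param testFractionRange length-2 range of test-set fractions.
#' @param seed integer seed.
#' @return A [ComparisonResult-class].
#' @export
monteCarloCV <- function(models, features, labels, nSamples = 1000L,
                         testFractionRange = c(0.05, 0.50), seed = 1L) {
    stopifnot(length(models) >= 1L, all(vapply(models, inherits,
                                               logical(1), "ModelSpec")))
    nSamples <- .checkScalarCount(nSamples, "nSamples")
    n <- nrow(features)
    nm <- vapply(models, `[[`, character(1), "name")
    if (anyDuplicated(nm)) stop("model names must be unique")
    auc <- acc <- matrix(NA_real_, nSamples, length(models),
                         dimnames = list(NULL, nm))
    set.seed(.deriveSeed(seed, 29L))
    for (s in seq_len(nSamples)) {
        ok <- FALSE
        for (try in seq_len(100L)) {
            frac <- stats::runif(1, testFractionRange[1], testFractionRange[2])
            nTest <- max(1L, round(frac * n))
            if (nTest >= n) next
            test <- sample.int(n, nTest)
            if (length(unique(labels[test])) == 2L &&
                length(unique(labels[-test])) == 2L) { ok <- TRUE; break }
        }
        if (!ok)
            stop("could not draw a two-class train/test split in 100 tries")
        for (j in seq_along(models)) {
            fit <- fitLogistic(features[-test, , drop = FALSE], labels[-test],
                               models[[j]]$predictors)
            p <- predict(fit, features[test, , drop = FALSE])
            auc[s, j] <- aucScore(p, labels[test])
            acc[s, j] <- mean((p >= 0.5) == (labels[test] == 1))
        }
    }
    summ <- data.frame(
        model = nm,
        mean_auc = colMeans(auc), sd_auc = apply(auc, 2, stats::sd),
        ci_low = apply(auc, 2, stats::quantile, 0.025),
        ci_high = apply(auc, 2, stats::quantile, 0.975),
        mean_accuracy = colMeans(acc), row.names = NULL)
    new("ComparisonResult", auc = auc, accuracy = acc, summary = summ,
        nSamples = nSamples, seed = as.integer(seed))
}

#' Classify models against the Parent Conservatism benchmark
#'
#' A model is `"above"`/`"below"` the benchmark when its 95% percentile
#' interval of AUC is disjoint from the benchmark's on the corresponding
#' side, `"indistinguishable"` otherwise.
#'
#' @param result a [ComparisonResult-class].
#' @param benchmark name of the benchmark model present in `result`.
#' @return `result`'s summary with a `vs_benchmark` column.
#' @export
compareToBenchmark <- function(result, benchmark = "Parent Conservatism") {
    stopifnot(is(result, "ComparisonResult"))
    summ <- result@summary
    bi <- match(benchmark, summ$model)
    if (is.na(bi)) stop("benchmark model '", benchmark, "' not in result")
    cls <- character(nrow(summ))
    for (i in seq_len(nrow(summ))) {
        if (i == bi) { cls[i] <- "indistinguishable"; next }
        if (summ$ci_low[i] > summ$ci_high[bi]) cls[i] <- "above"
        else if (summ$ci_high[i] < summ$ci_low[bi]) cls[i] <- "below"
        else cls[i] <- "indistinguishable"
    }
    summ$vs_benchmark <- cls
    summ
}
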