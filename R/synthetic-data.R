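#' Ideology histogram of the reference cohort
#'
#' Default 6-point ideology counts used by the simulator: 24/52/49/36/9/4
#' from Very liberal (1) to Very conservative (6), n = 174.
#'
#' @return Integer vector of length 6.
#' @export
referenceIdeologyCounts <- function() c(24L, 52L, 49L, 36L, 9L, 4L)

#' Reference covariate-ideology correlation targets
#'
#' Default target correlations between each survey covariate and the
#' 6-point ideology, matching the descriptive structure of the reference
#' cohort (e.g. mother's conservatism 0.417, father's conservatism 0.349).
#'
#' @return Named numeric vector over the survey covariates.
#' @export
referenceCovariateTargets <- function() {
    c(male = 0.180, age = -0.133, education = -0.137,
      father_education = 0.113, mother_education = 0.081,
      father_conservatism = 0.349, mother_conservatism = 0.417,
      income = -0.051, parent_income = 0.194, religiosity = 0.279,
      origin_city_conservatism = 0.054, current_city_conservatism = -0.007)
}

# Marginal distributions (as probabilities) of each covariate, taken from
# the reference cohort's printed Likert response counts; ages follow a
# right-skewed discrete distribution over 18..40 with mean near 21.4.
.cohortMarginals <- function() {
    n <- 174
    agep <- exp(-(0:22) / 4)
    list(
        male = list(values = c(0L, 1L), probs = c(113, 61) / n),
        age = list(values = 18:40, probs = agep / sum(agep)),
        education = list(values = 1:5, probs = c(4, 131, 12, 8, 19) / n),
        father_education = list(values = 1:5, probs = c(32, 20, 60, 8, 54) / n),
        mother_education = list(values = 1:5, probs = c(29, 25, 76, 13, 31) / n),
        father_conservatism = list(values = 1:6,
                                   probs = c(5, 28, 33, 41, 37, 30) / n),
        mother_conservatism = list(values = 1:6,
                                   probs = c(9, 37, 46, 35, 31, 16) / n),
        income = list(values = 1:6, probs = c(164, 9, 1, 0, 0, 0) / n),
        parent_income = list(values = 1:6,
                             probs = c(20, 22, 35, 29, 39, 29) / n),
        religiosity = list(values = 1:6, probs = c(44, 40, 24, 29, 26, 11) / n),
        origin_city_conservatism = list(values = 1:6,
                                        probs = c(1, 17, 44, 57, 40, 15) / n),
        current_city_conservatism = list(values = 1:6,
                                         probs = c(16, 64, 64, 23, 6, 1) / n))
}

# Correlation attenuation from discretizing a standard normal latent into
# bins with the given probabilities/values: corr(D, Z) where D is the
# binned value. Used to pre-compensate copula correlations so the realized
# discrete correlation hits the target.
.discretizationAttenuation <- function(values, probs) {
    cum <- cumsum(probs)
    bounds <- c(-Inf, stats::qnorm(pmin(cum, 1)))
    phi <- stats::dnorm(bounds)
    phi[!is.finite(bounds)] <- 0
    covDZ <- sum(values * (phi[-length(phi)] - phi[-1]))
    mu <- sum(values * probs)
    sdD <- sqrt(sum(values^2 * probs) - mu^2)
    if (sdD == 0) return(1)
    covDZ / sdD
}

#' Generate a synthetic cohort with a fixed ideology histogram
#'
#' Ideology levels are assigned deterministically to match
#' `ideologyCounts` exactly, then shuffled by seed. Each survey covariate
#' is generated from a latent-Gaussian copula tied to standardized
#' ideology at the requested target correlation and discretized to its
#' Likert range; the copula correlation is pre-compensated for
#' discretization attenuation so realized correlations converge on the
#' target as n grows.
#'
#' @param n number of subjects.
#' @param ideologyCounts length-6 integer vector summing to `n`.
#' @param covariateTargets named vector of target covariate-ideology
#'   correlations in (-1, 1); defaults to [referenceCovariateTargets()].
#'   Covariates not named get target 0.
#' @param seed integer seed.
#' @return A [Cohort-class].
#' @examples
#' coh <- generateCohort(174, seed = 1)
#' tabulate(ideology(coh), 6)
#' @export
generateCohort <- function(n = 174L,
                           ideologyCounts = referenceIdeologyCounts(),
                           covariateTargets = referenceCovariateTargets(),
                           seed = 1L) {
    n <- .checkScalarCount(n, "n")
    if (length(ideologyCounts) != 6L || sum(ideologyCounts) != n)
        stop("ideologyCounts must have length 6 and sum to n")
    if (any(abs(covariateTargets) >= 1))
        stop("covariate targets must lie in (-1, 1)")
    marg <- .cohortMarginals()
    bad <- setdiff(names(covariateTargets), names(marg))
    if (length(bad)) stop("unknown covariates: ", paste(bad, collapse = ", "))

    set.seed(.deriveSeed(seed, 1L))
    ideo <- sample(rep.int(1:6, ideologyCounts))
    z <- if (stats::sd(ideo) > 0) .standardize(ideo) else rep(0, n)

    d <- data.frame(subject_id = sprintf("S%03d", seq_len(n)))
    for (v in names(marg)) {
        target <- if (v %in% names(covariateTargets)) covariateTargets[[v]] else 0
        lam <- .discretizationAttenuation(marg[[v]]$values, marg[[v]]$probs)
        rho <- max(-0.99, min(0.99, target / lam))
        x <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
        cut <- stats::qnorm(cumsum(marg[[v]]$probs))
        cut <- cut[-length(cut)]
        d[[v]] <- marg[[v]]$values[findInterval(x, cut) + 1L]
    }
    d$conservatism <- ideo
    new("Cohort", data = d[, .COHORT_COLS])
}

#' Declare planted edge-ideology associations for the simulator
#'
#' @param edges data.frame with columns `task`, `roi_i`, `roi_j`,
#'   `effect`; `effect` is the slope of the edge's latent correlation on
#'   standardized ideology. Pass a zero-row frame for a null world.
#' @param baseCorr baseline latent correlation of each signal edge at
#'   average ideology.
#' @param noiseSd standard deviation of the BOLD noise.
#' @param seed integer seed used by [generateBoldTimeSeries()].
#' @return A [PlantedTruth-class].
#' @export
plantedTruth <- function(edges = data.frame(task = character(0),
                                            roi_i = integer(0),
                                            roi_j = integer(0),
                                            effect = numeric(0)),
                         baseCorr = 0.35, noiseSd = 1, seed = 1L) {
    new("PlantedTruth", edges = edges, baseCorr = baseCorr,
        noiseSd = noiseSd, seed = as.integer(seed))
}

#' Simulate ROI-averaged BOLD time series with planted FC signal
#'
#' For every subject and task a T x R noise matrix is generated; each
#' planted edge (i, j) receives a shared latent factor whose loadings give
#' the pair a correlation of `baseCorr + effect * z` where z is the
#' subject's standardized ideology. An optional task design adds a common
#' task-evoked component to every ROI (so FC is confounded until the
#' design is regressed out), and an optional ROI column is set entirely
#' missing to emulate a dead parcel.
#'
#' @param cohort a [Cohort-class].
#' @param truth a [PlantedTruth-class].
#' @param nRois number of ROIs (must cover all planted indices).
#' @param nTimepoints number of scans per series (>= 30).
#' @param tasks character vector of task identifiers.
#' @param missingRoi single ROI index rendered all-missing, or `NULL`.
#' @param taskDesign optional T x K design matrix of task regressors.
#' @param designCoef length-K coefficients of the task component.
#' @return Named list of [RoiTimeSeries-class], names `"<subject>.<task>"`.
#' @export
generateBoldTimeSeries <- function(cohort, truth, nRois, nTimepoints = 150L,
                                   tasks = paste0("task", 1:9),
                                   missingRoi = NULL, taskDesign = NULL,
                                   designCoef = NULL) {
    stopifnot(is(cohort, "Cohort"), is(truth, "PlantedTruth"))
    nRois <- .checkScalarCount(nRois, "nRois", 2L)
    nT <- .checkScalarCount(nTimepoints, "nTimepoints", 30L)
    edges <- truth@edges
    if (nrow(edges) && max(edges$roi_i, edges$roi_j) > nRois)
        stop("nRois smaller than the largest planted ROI index")
    if (!is.null(taskDesign)) {
        taskDesign <- as.matrix(taskDesign)
        if (nrow(taskDesign) != nT) stop("taskDesign must have nTimepoints rows")
        if (is.null(designCoef)) designCoef <- rep(1, ncol(taskDesign))
    }
    ids <- subjectIds(cohort)
    y <- ideology(cohort)
    z <- if (stats::sd(y) > 0) .standardize(y) else rep(0, length(y))

    set.seed(.deriveSeed(truth@seed, 7L))
    out <- vector("list", length(ids) * length(tasks))
    names(out) <- as.vector(t(outer(ids, tasks, paste, sep = ".")))
    for (k in seq_along(ids)) {
        for (tk in tasks) {
            X <- matrix(stats::rnorm(nT * nRois), nT, nRois)
            et <- edges[edges$task == tk, , drop = FALSE]
            if (nrow(et)) {
                rho <- truth@baseCorr + et$effect * z[k]
                if (any(abs(rho) >= 1))
                    stop("planted effect drives a correlation outside (-1, 1) ",
                         "for subject ", ids[k])
                load2 <- abs(rho)
                s <- numeric(nRois)
                for (e in seq_len(nrow(et)))
                    s[c(et$roi_i[e], et$roi_j[e])] <-
                        s[c(et$roi_i[e], et$roi_j[e])] + load2[e]
                if (any(s >= 1))
                    stop("combined planted loadings exceed unit variance at a ROI")
                touched <- which(s > 0)
                X[, touched] <- sweep(X[, touched, drop = FALSE], 2,
                                      sqrt(1 - s[touched]), `*`)
                for (e in seq_len(nrow(et))) {
                    f <- stats::rnorm(nT)
                    X[, et$roi_i[e]] <- X[, et$roi_i[e]] + sqrt(load2[e]) * f
                    X[, et$roi_j[e]] <- X[, et$roi_j[e]] +
                        sign(rho[e]) * sqrt(load2[e]) * f
                }
            }
            X <- X * truth@noiseSd
            if (!is.null(taskDesign))
                X <- X + drop(taskDesign %*% designCoef)
            miss <- integer(0)
            if (!is.null(missingRoi)) {
                miss <- as.integer(missingRoi)
                X[, miss] <- NA_real_
            }
            out[[paste(ids[k], tk, sep = ".")]] <-
                new("RoiTimeSeries", subjectId = ids[k], taskId = tk,
                    data = X, missingRois = miss)
        }
    }
    out
}

#' Simulate an out-of-fold score matrix with known task-ideology signal
#'
#' Generates a subjects x tasks score matrix in which column t has
#' population correlation `taskSignal[t]` with the cohort's ideology,
#' bypassing network training. Scores are placed on the 1-6 Likert scale
#' (mean and SD of the true ideology). This lets the score-analysis,
#' model-comparison and importance stages be tested against known signal
#' without the cost of fitting networks.
#'
#' @param cohort a [Cohort-class].
#' @param taskSignal numeric vector of target correlations in (-1, 1),
#'   one per task.
#' @param seed integer seed.
#' @param tasks task names (defaults to `task1..taskT`).
#' @return An [IdeologyScoreMatrix-class] without fold models.
#' @export
generateScoreMatrix <- function(cohort, taskSignal = rep(0, 9), seed = 1L,
                                tasks = NULL) {
    stopifnot(is(cohort, "Cohort"))
    if (any(abs(taskSignal) >= 1)) stop("taskSignal must lie in (-1, 1)")
    if (is.null(tasks)) tasks <- paste0("task", seq_along(taskSignal))
    stopifnot(length(tasks) == length(taskSignal))
    y <- ideology(cohort)
    n <- length(y)
    z <- .standardize(y)
    set.seed(.deriveSeed(seed, 11L))
    S <- vapply(taskSignal, function(r)
        mean(y) + stats::sd(y) * (r * z + sqrt(1 - r^2) * stats::rnorm(n)),
        numeric(n))
    dimnames(S) <- list(subjectIds(cohort), tasks)
    new("IdeologyScoreMatrix", scores = S, foldAssignment = integer(0),
        models = list(), seed = as.integer(seed))
}
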