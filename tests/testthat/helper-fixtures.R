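# Shared fixtures; everything is generated in code at test time.

# Small cohort with a roughly reference-shaped ideology histogram.
tinyCohort <- function(n = 60, seed = 1) {
    counts <- round(referenceIdeologyCounts() * n / 174)
    counts[2] <- counts[2] + (n - sum(counts))
    generateCohort(n, counts, seed = seed)
}

# Random symmetric zero-diagonal matrix scaled into [-1, 1].
randomFC <- function(R, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    M <- matrix(rnorm(R * R), R)
    M <- (M + t(M)) / 2
    diag(M) <- 0
    M / (max(abs(M)) + 0.1)
}

quickSpace <- function(nEpochs = 20L, nFilters = 8L, nUnits = 4L,
                       lr = 0.01, nDraws = 1L)
    searchSpace(nE2nFilters = nFilters, nN2gUnits = nUnits,
                learningRate = lr, nEpochs = nEpochs, batchSize = 16L,
                nDraws = nDraws)

# Parameters realizing the exact linear functional
#   score(E) = sum_ij s_i r_j Ehat_ij + b3
# through the nonlinear network, using the identity
#   x = (3/4) (f(x) - f(-x)) for the very leaky ReLU f.
linearParams <- function(s, r, b3 = 0) {
    R <- length(s)
    A <- cbind(r, -r)                       # two mirrored E2N filters
    B <- matrix(0, R, 2)
    # N2G unit m weights over (i, f) column-major: f = 1 block then f = 2
    w1 <- c(3 / 4 * s, -3 / 4 * s)
    W <- rbind(w1, -w1)
    list(A = A, B = B, b1 = c(0, 0), W = W, b2 = c(0, 0),
         w3 = c(3 / 4, -3 / 4), b3 = b3,
         bnMean = matrix(0, R, R), bnSd = matrix(1, R, R))
}

linearConfig <- function() networkConfig(nE2nFilters = 2L, nN2gUnits = 2L)

# One-call planted-signal dataset: two signal edges in task1 with
# opposite effects, optional extra null tasks.
plantedWorld <- function(seed, nSubjects = 174, nRois = 40,
                         tasks = paste0("task", 1:9),
                         effect = 0.15, baseCorr = 0.35,
                         covariateTargets = referenceCovariateTargets()) {
    counts <- round(referenceIdeologyCounts() * nSubjects / 174)
    counts[2] <- counts[2] + (nSubjects - sum(counts))
    cohort <- generateCohort(nSubjects, counts, covariateTargets,
                             seed = seed)
    truth <- plantedTruth(
        data.frame(task = "task1", roi_i = c(3L, 12L), roi_j = c(7L, 20L),
                   effect = c(effect, -effect)),
        baseCorr = baseCorr, seed = seed)
    series <- generateBoldTimeSeries(cohort, truth, nRois = nRois,
                                     nTimepoints = 150L, tasks = tasks)
    list(cohort = cohort, truth = truth,
         dataset = assembleDataset(series))
}
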