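#' Configuration of the connectome regression network
#'
#' Dropout rate (0.5, applied after the node-to-graph layer) and the very
#' leaky ReLU slope (1/3) are architectural constants and cannot be
#' changed; the remaining fields are training hyperparameters exposed to
#' random search.
#'
#' @param nE2nFilters number of edge-to-node filters.
#' @param nN2gUnits number of node-to-graph units.
#' @param learningRate SGD step size.
#' @param nEpochs number of passes over the training set.
#' @param batchSize minibatch size.
#' @param momentum SGD momentum coefficient.
#' @param weightDecay L2 penalty on weights (not biases).
#' @param maxGradNorm clip the global gradient norm to this value each
#'   step (`Inf` disables); guards minibatch SGD against divergence at
#'   aggressive learning rates.
#' @param tieWeights constrain row and column E2N weights to be equal
#'   (they are redundant in expectation since FC matrices are symmetric).
#' @param dropoutRate,leakSlope fixed at 0.5 and 1/3; supplied values are
#'   validated, not free.
#' @return A classed list of settings.
#' @export
networkConfig <- function(nE2nFilters = 8L, nN2gUnits = 4L,
                          learningRate = 0.01, nEpochs = 50L,
                          batchSize = 16L, momentum = 0.9,
                          weightDecay = 1e-4, maxGradNorm = 5,
                          tieWeights = FALSE,
                          dropoutRate = 0.5, leakSlope = 1 / 3) {
    if (!isTRUE(all.equal(dropoutRate, 0.5)))
        stop("dropoutRate is fixed at 0.5")
    if (!isTRUE(all.equal(leakSlope, 1 / 3)))
        stop("leakSlope is fixed at 1/3")
    cfg <- list(nE2nFilters = .checkScalarCount(nE2nFilters, "nE2nFilters"),
                nN2gUnits = .checkScalarCount(nN2gUnits, "nN2gUnits"),
                learningRate = learningRate, nEpochs =
                    .checkScalarCount(nEpochs, "nEpochs"),
                batchSize = .checkScalarCount(batchSize, "batchSize", 2L),
                momentum = momentum, weightDecay = weightDecay,
                maxGradNorm = maxGradNorm,
                tieWeights = isTRUE(tieWeights),
                dropoutRate = 0.5, leakSlope = 1 / 3)
    class(cfg) <- "NetworkConfig"
    cfg
}

#' Define a random-search space over training hyperparameters
#'
#' Each entry is either a vector of discrete choices (drawn uniformly) or
#' a `list(min =, max =, log = TRUE/FALSE)` continuous range. Defaults
#' follow common connectome-CNN practice: filters in \{16, 32, 64\},
#' learning rate log-uniform on 1e-4..1e-2, epochs in \{50, 100, 200\},
#' batch size in \{8, 16\}.
#'
#' @param nE2nFilters,nN2gUnits,learningRate,nEpochs,batchSize search
#'   ranges per hyperparameter.
#' @param nDraws number of random configurations drawn per search.
#' @return A classed list.
#' @export
searchSpace <- function(nE2nFilters = c(16L, 32L, 64L),
                        nN2gUnits = c(8L, 16L, 32L),
                        learningRate = list(min = 1e-4, max = 1e-2,
                                            log = TRUE),
                        nEpochs = c(50L, 100L, 200L),
                        batchSize = c(8L, 16L),
                        nDraws = 10L) {
    sp <- list(nE2nFilters = nE2nFilters, nN2gUnits = nN2gUnits,
               learningRate = learningRate, nEpochs = nEpochs,
               batchSize = batchSize,
               nDraws = .checkScalarCount(nDraws, "nDraws"))
    for (nm in setdiff(names(sp), "nDraws"))
        if (length(sp[[nm]]) == 0) stop("empty range for ", nm)
    class(sp) <- "SearchSpace"
    sp
}

.drawOne <- function(range) {
    if (is.list(range)) {
        u <- stats::runif(1)
        if (isTRUE(range$log))
            exp(log(range$min) + u * (log(range$max) - log(range$min)))
        else range$min + u * (range$max - range$min)
    } else if (length(range) == 1L) {
        range
    } else {
        range[sample.int(length(range), 1L)]
    }
}

#' Draw candidate configurations from a search space
#'
#' @param space a [searchSpace()].
#' @param seed integer seed; identical seeds give identical draws.
#' @return List of [networkConfig()] objects, length `space$nDraws`.
#' @export
sampleHyperparameters <- function(space, seed = 1L) {
    stopifnot(inherits(space, "SearchSpace"))
    set.seed(.deriveSeed(seed, 13L))
    lapply(seq_len(space$nDraws), function(i)
        networkConfig(
            nE2nFilters = .drawOne(space$nE2nFilters),
            nN2gUnits = .drawOne(space$nN2gUnits),
            learningRate = .drawOne(space$learningRate),
            nEpochs = .drawOne(space$nEpochs),
            batchSize = .drawOne(space$batchSize)))
}

# Convert a list of FCMatrix (or matrices) to an R x R x n array.
.toArray <- function(mats) {
    mats <- lapply(mats, function(m) if (is(m, "FCMatrix")) fcValues(m) else m)
    R <- nrow(mats[[1]])
    arr <- array(unlist(mats, use.names = FALSE), c(R, R, length(mats)))
    arr
}

#' Train the connectome network by minibatch gradient descent
#'
#' Minimizes the Euclidean (mean squared) loss between predicted and true
#' scores by SGD with momentum. Inputs are normalized per edge over each
#' minibatch during training; the training-set statistics are stored for
#' deterministic evaluation-mode prediction. Dropout (rate 0.5) follows
#' the node-to-graph activation.
#'
#' @param mats list of [FCMatrix-class]/matrices or an R x R x n array.
#' @param y numeric targets on the 1-6 scale.
#' @param config a [networkConfig()].
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @return List with elements `params`, `config`, `trainLoss` (final
#'   evaluation-mode MSE on the training data) and `lossTrace`.
#' @export
trainNetwork <- function(mats, y, config = networkConfig(), seed = 1L) {
    arr <- if (is.array(mats) && length(dim(mats)) == 3L) mats
           else .toArray(mats)
    n <- dim(arr)[3]; R <- dim(arr)[1]
    stopifnot(length(y) == n, n >= 2L)
    set.seed(.deriveSeed(seed, 17L))
    params <- .initParams(R, config)
    if (config$tieWeights) params$B <- params$A
    params$b3 <- mean(y)
    vel <- lapply(params[c("A", "B", "b1", "W", "b2", "w3", "b3")],
                  function(p) p * 0)
    decayed <- c("A", "B", "W", "w3")
    lossTrace <- numeric(config$nEpochs)
    for (ep in seq_len(config$nEpochs)) {
        ord <- sample.int(n)
        bsz <- min(config$batchSize, n)
        starts <- seq(1L, n, by = bsz)
        epLoss <- 0
        for (st in starts) {
            idx <- ord[st:min(st + bsz - 1L, n)]
            if (length(idx) < 2L) next  # batch stats need >= 2 samples
            cc <- .nnForward(arr[, , idx, drop = FALSE], params, config,
                             training = TRUE, cache = TRUE)
            loss <- mean((cc$score - y[idx])^2)
            if (!is.finite(loss))
                stop("non-finite training loss at epoch ", ep,
                     " (learning rate ", signif(config$learningRate, 3),
                     "); training aborted")
            epLoss <- epLoss + loss * length(idx)
            g <- .nnBackward(cc, params, config, y[idx])
            gn <- sqrt(sum(vapply(g, function(x) sum(x^2), numeric(1))))
            if (is.finite(config$maxGradNorm) && gn > config$maxGradNorm)
                g <- lapply(g, `*`, config$maxGradNorm / gn)
            if (config$tieWeights) {
                g$A <- g$A + g$B
                g$B <- g$A
            }
            for (nm in names(vel)) {
                pen <- if (nm %in% decayed) config$weightDecay else 0
                vel[[nm]] <- config$momentum * vel[[nm]] -
                    config$learningRate * (g[[nm]] + pen * params[[nm]])
                params[[nm]] <- params[[nm]] + vel[[nm]]
            }
        }
        lossTrace[ep] <- epLoss / n
    }
    bn <- .batchNormStats(arr)
    params$bnMean <- bn$mean
    params$bnSd <- bn$sd
    pred <- .nnForward(arr, params, config, training = FALSE)
    list(params = params, config = config,
         trainLoss = mean((pred - y)^2), lossTrace = lossTrace)
}

#' Fit one cross-validation fold with random hyperparameter search
#'
#' Draws `space$nDraws` candidate configurations, trains each on the
#' training matrices, and returns the fit whose final evaluation-mode
#' training loss is minimal, so tuning touches training data only.
#'
#' @param mats training FC matrices (list or array).
#' @param y training targets on the 1-6 scale.
#' @param space a [searchSpace()].
#' @param seed integer seed.
#' @return The winning [trainNetwork()] fit, with `searchLosses` attached.
#' @export
fitFold <- function(mats, y, space = searchSpace(), seed = 1L) {
    configs <- sampleHyperparameters(space, seed)
    fits <- lapply(seq_along(configs), function(i)
        trainNetwork(mats, y, configs[[i]], seed = .deriveSeed(seed, 19L + i)))
    losses <- vapply(fits, `[[`, numeric(1), "trainLoss")
    best <- fits[[which.min(losses)]]
    best$searchLosses <- losses
    best
}

#' Out-of-fold ideology scores from k-fold cross-validation
#'
#' Subjects are partitioned into k folds once (seeded; optionally
#' stratified by ideology) and the same folds are reused for every task.
#' For each task and fold, the network is tuned and trained on the
#' training folds only and then scores the held-out subjects, so no score
#' ever comes from a model that saw its subject.
#'
#' @param dataset an [FCDataset-class].
#' @param cohort a [Cohort-class] aligned with the dataset's subjects.
#' @param k number of folds (default 10; k = n gives leave-one-out).
#' @param space a [searchSpace()].
#' @param seed integer seed.
#' @param stratify balance folds over ideology levels.
#' @param keepModels retain the fitted fold models (needed for saliency).
#' @return An [IdeologyScoreMatrix-class].
#' @export
crossValidatedScores <- function(dataset, cohort, k = 10L,
                                 space = searchSpace(), seed = 1L,
                                 stratify = FALSE, keepModels = TRUE) {
    stopifnot(is(dataset, "FCDataset"), is(cohort, "Cohort"))
    ids <- subjectIds(dataset)
    if (!setequal(ids, subjectIds(cohort)))
        stop("dataset and cohort subjects differ")
    y <- ideology(cohort)[match(ids, subjectIds(cohort))]
    n <- length(ids)
    k <- .checkScalarCount(k, "k", 2L)
    if (k > n) stop("k exceeds the number of subjects")

    set.seed(.deriveSeed(seed, 23L))
    if (stratify) {
        folds <- integer(n)
        for (lev in unique(y)) {
            who <- which(y == lev)
            folds[who] <- sample(rep_len(seq_len(k), length(who)))
        }
    } else {
        folds <- sample(rep_len(seq_len(k), n))
    }

    tasks <- taskIds(dataset)
    scores <- matrix(NA_real_, n, length(tasks),
                     dimnames = list(ids, tasks))
    models <- if (keepModels)
        stats::setNames(rep(list(vector("list", k)), length(tasks)), tasks)
    else list()
    for (ti in seq_along(tasks)) {
        arr <- .toArray(lapply(ids, function(s)
            getFC(dataset, s, tasks[ti])))
        for (f in seq_len(k)) {
            test <- which(folds == f)
            train <- which(folds != f)
            fit <- fitFold(arr[, , train, drop = FALSE], y[train], space,
                           seed = .deriveSeed(seed, 100L + 31L * ti + f))
            scores[test, ti] <- .nnForward(
                arr[, , test, drop = FALSE], fit$params, fit$config,
                training = FALSE)
            if (keepModels)
                models[[ti]][[f]] <- list(params = fit$params,
                                          config = fit$config)
        }
    }
    new("IdeologyScoreMatrix", scores = scores,
        foldAssignment = as.integer(folds), models = models,
        seed = as.integer(seed))
}
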