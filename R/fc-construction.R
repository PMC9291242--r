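#' Regress task-evoked activation out of a BOLD time series
#'
#' Replaces every non-missing ROI column by its residual from an ordinary
#' least squares fit on an intercept plus the task design, removing
#' stimulus-locked activation before connectivity is computed. Residual
#' columns are orthogonal to every design column.
#'
#' @param ts a [RoiTimeSeries-class].
#' @param design numeric T x K matrix of task regressors (no intercept
#'   column; one is added). Must have full column rank jointly with the
#'   intercept.
#' @return A [RoiTimeSeries-class] of residuals (missing columns kept
#'   missing).
#' @export
regressOutTask <- function(ts, design) {
    stopifnot(is(ts, "RoiTimeSeries"))
    design <- as.matrix(design)
    X <- ts@data
    if (nrow(design) != nrow(X))
        stop("design has ", nrow(design), " rows but series has ", nrow(X))
    M <- cbind(intercept = 1, design)
    qrM <- qr(M)
    if (qrM$rank < ncol(M))
        stop("design matrix is rank deficient after adding an intercept")
    keep <- setdiff(seq_len(ncol(X)), ts@missingRois)
    res <- X
    res[, keep] <- qr.resid(qrM, X[, keep, drop = FALSE])
    new("RoiTimeSeries", subjectId = ts@subjectId, taskId = ts@taskId,
        data = res, missingRois = ts@missingRois)
}

#' Compute a functional connectivity matrix from one time series
#'
#' Pairwise Pearson correlation of retained ROI columns. ROIs that are
#' entirely missing or have zero variance are dropped and recorded via
#' `roiLabels` (zero-variance columns make the correlation undefined, so
#' the exclusion rule extends the all-missing case). The diagonal is set
#' to exactly zero.
#'
#' @param ts a [RoiTimeSeries-class] with at least 3 timepoints and at
#'   least 2 retainable ROIs.
#' @return An [FCMatrix-class].
#' @examples
#' ts <- new("RoiTimeSeries", subjectId = "S1", taskId = "rest",
#'           data = matrix(rnorm(300), 100, 3), missingRois = integer(0))
#' fc <- computeFC(ts)
#' @export
computeFC <- function(ts) {
    stopifnot(is(ts, "RoiTimeSeries"))
    X <- ts@data
    if (nrow(X) < 3L) stop("need at least 3 timepoints for correlation")
    sds <- apply(X, 2, stats::sd)
    drop <- union(ts@missingRois,
                  which(!is.finite(sds) | sds == 0))
    keep <- setdiff(seq_len(ncol(X)), drop)
    if (length(keep) < 2L)
        stop("fewer than 2 retainable ROIs (", length(drop), " excluded)")
    E <- stats::cor(X[, keep, drop = FALSE])
    E <- (E + t(E)) / 2
    diag(E) <- 0
    dimnames(E) <- NULL
    new("FCMatrix", subjectId = ts@subjectId, taskId = ts@taskId,
        E = E, roiLabels = as.integer(keep))
}

#' Assemble a harmonized FC dataset from all subject-task series
#'
#' Applies the optional per-task design regression, computes one FC
#' matrix per subject and task, and restricts all matrices to the
#' intersection of retained ROIs so every matrix shares identical
#' dimensions and labels. A manifest records, per series, how many ROIs
#' each series originally retained.
#'
#' @param series named list of [RoiTimeSeries-class]; every subject must
#'   have every task.
#' @param designs optional named list, task -> design matrix, passed to
#'   [regressOutTask()].
#' @return An [FCDataset-class].
#' @export
assembleDataset <- function(series, designs = NULL) {
    stopifnot(length(series) > 0)
    subjects <- unique(vapply(series, function(s) s@subjectId, character(1)))
    tasks <- unique(vapply(series, function(s) s@taskId, character(1)))
    keys <- vapply(series, function(s) paste(s@subjectId, s@taskId, sep = "."),
                   character(1))
    names(series) <- keys
    for (su in subjects) for (tk in tasks)
        if (!paste(su, tk, sep = ".") %in% keys)
            stop("subject ", su, " is missing task ", tk)

    mats <- lapply(series, function(s) {
        if (!is.null(designs) && !is.null(designs[[s@taskId]]))
            s <- regressOutTask(s, designs[[s@taskId]])
        computeFC(s)
    })
    nOriginal <- vapply(series, function(s) ncol(s@data), integer(1))
    nOwn <- vapply(mats, function(m) length(m@roiLabels), integer(1))
    common <- Reduce(intersect, lapply(mats, function(m) m@roiLabels))
    if (length(common) < 2L)
        stop("fewer than 2 ROIs retained across the whole dataset")
    common <- sort(as.integer(common))
    mats <- lapply(mats, function(m) {
        idx <- match(common, m@roiLabels)
        E <- m@E[idx, idx, drop = FALSE]
        new("FCMatrix", subjectId = m@subjectId, taskId = m@taskId,
            E = E, roiLabels = common)
    })
    manifest <- data.frame(
        subject = vapply(mats, function(m) m@subjectId, character(1)),
        task = vapply(mats, function(m) m@taskId, character(1)),
        n_rois_input = nOriginal,
        n_rois_own = nOwn,
        n_rois_retained = length(common),
        row.names = NULL)
    new("FCDataset", matrices = mats, subjects = subjects, tasks = tasks,
        roiLabels = common, manifest = manifest)
}
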