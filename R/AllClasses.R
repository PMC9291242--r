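#' @import methods
NULL

.LIKERT5 <- c("education", "father_education", "mother_education")
.LIKERT6 <- c("father_conservatism", "mother_conservatism", "income",
              "parent_income", "religiosity", "origin_city_conservatism",
              "current_city_conservatism", "conservatism")
.COHORT_COLS <- c("subject_id", "male", "age", .LIKERT5, .LIKERT6)

#' Cohort of subjects with survey covariates and 6-point ideology
#'
#' Container for the per-subject survey table: demographic covariates on
#' Likert scales and the self-reported ideology outcome on a 6-point scale
#' (1 = Very liberal ... 6 = Very conservative). Validity enforces the
#' Likert ranges, integer coding, uniqueness of subject identifiers and
#' absence of missing values.
#'
#' @slot data data.frame with one row per subject; see [generateCohort()]
#'   for the required columns.
#' @seealso [generateCohort()], [readCohort()], [ideology()]
#' @export
setClass("Cohort", representation(data = "data.frame"))

setValidity("Cohort", function(object) {
    d <- object@data
    msg <- character(0)
    missing_cols <- setdiff(.COHORT_COLS, names(d))
    if (length(missing_cols))
        return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
    if (anyNA(d))
        msg <- c(msg, "cohort contains missing values")
    if (anyDuplicated(d$subject_id))
        msg <- c(msg, "subject_id values are not unique")
    if (!all(d$male %in% c(0L, 1L)))
        msg <- c(msg, "male must be binary 0/1")
    for (col in c(.LIKERT5, .LIKERT6)) {
        hi <- if (col %in% .LIKERT5) 5L else 6L
        v <- d[[col]]
        if (!all(v == round(v)) || any(v < 1L) || any(v > hi))
            msg <- c(msg, sprintf("%s outside integer range 1..%d", col, hi))
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' ROI-averaged BOLD time series for one subject and task
#'
#' A T x R matrix of region-averaged BOLD signal for one scanning session.
#' ROIs whose whole column is missing (encoded as `NA`, never as zeros) are
#' listed in `missingRois` so that downstream exclusion logic is explicit
#' and testable.
#'
#' @slot subjectId,taskId character identifiers.
#' @slot data numeric matrix, timepoints x ROIs.
#' @slot missingRois integer indices of all-missing ROI columns.
#' @export
setClass("RoiTimeSeries", representation(
    subjectId = "character", taskId = "character",
    data = "matrix", missingRois = "integer"))

setValidity("RoiTimeSeries", function(object) {
    d <- object@data
    if (nrow(d) < 2L) return("need at least 2 timepoints")
    miss <- object@missingRois
    if (length(miss) && (any(miss < 1L) || any(miss > ncol(d))))
        return("missingRois out of range")
    if (length(miss) && !all(colSums(is.na(d[, miss, drop = FALSE])) == nrow(d)))
        return("columns in missingRois must be entirely missing")
    keep <- setdiff(seq_len(ncol(d)), miss)
    if (length(keep) && !all(is.finite(d[, keep])))
        return("non-missing ROI columns must be finite")
    TRUE
})

#' Functional connectivity matrix for one subject and task
#'
#' Symmetric matrix of pairwise Pearson correlations between retained ROI
#' time series, zero along the diagonal, off-diagonal entries in [-1, 1].
#' `roiLabels` preserves the original (1-based) ROI indices of the retained
#' columns so excluded ROIs remain traceable.
#'
#' @slot subjectId,taskId character identifiers.
#' @slot E numeric R x R correlation matrix.
#' @slot roiLabels integer original indices of retained ROIs.
#' @seealso [computeFC()]
#' @export
setClass("FCMatrix", representation(
    subjectId = "character", taskId = "character",
    E = "matrix", roiLabels = "integer"))

setValidity("FCMatrix", function(object) {
    E <- object@E
    if (nrow(E) != ncol(E)) return("E must be square")
    if (length(object@roiLabels) != nrow(E))
        return("roiLabels length must equal matrix dimension")
    if (any(abs(diag(E)) > 1e-12)) return("diagonal must be exactly 0")
    if (max(abs(E - t(E))) > 1e-8) return("E must be symmetric")
    if (any(E < -1 - 1e-8) || any(E > 1 + 1e-8))
        return("entries must lie in [-1, 1]")
    TRUE
})

#' Dataset of FC matrices for all subjects and tasks
#'
#' Holds one [FCMatrix-class] per (subject, task), harmonized so that all
#' matrices share an identical retained-ROI set, together with a manifest
#' of exclusions.
#'
#' @slot matrices named list of FCMatrix, names `"<subject>.<task>"`.
#' @slot subjects,tasks character vectors.
#' @slot roiLabels shared retained ROI indices.
#' @slot manifest data.frame recording per-series exclusions.
#' @seealso [assembleDataset()]
#' @export
setClass("FCDataset", representation(
    matrices = "list", subjects = "character", tasks = "character",
    roiLabels = "integer", manifest = "data.frame"))

setValidity("FCDataset", function(object) {
    expect <- as.vector(outer(object@subjects, object@tasks, paste, sep = "."))
    if (!setequal(names(object@matrices), expect))
        return("matrices must cover every subject-task combination")
    for (m in object@matrices)
        if (!identical(m@roiLabels, object@roiLabels))
            return("all matrices must share identical roiLabels")
    TRUE
})

#' Out-of-fold continuous ideology scores, subjects x tasks
#'
#' Each column holds the continuous network prediction of the 6-point
#' ideology for one task; entry (k, t) was produced by the model trained
#' with subject k's fold held out, so no score ever reflects a model that
#' saw its own subject. Fitted fold models are retained (when requested)
#' for gradient saliency.
#'
#' @slot scores numeric matrix, subjects x tasks, dimnames set.
#' @slot foldAssignment integer fold index per subject (may be empty for
#'   simulated score matrices that bypass training).
#' @slot models list, `models[[task]][[fold]]` = fitted parameters.
#' @slot seed integer seed the scores were produced under.
#' @seealso [crossValidatedScores()], [generateScoreMatrix()]
#' @export
setClass("IdeologyScoreMatrix", representation(
    scores = "matrix", foldAssignment = "integer",
    models = "list", seed = "integer"))

setValidity("IdeologyScoreMatrix", function(object) {
    if (!all(is.finite(object@scores))) return("scores must be finite")
    fa <- object@foldAssignment
    if (length(fa) && length(fa) != nrow(object@scores))
        return("foldAssignment length must match number of subjects")
    if (is.null(rownames(object@scores)) || is.null(colnames(object@scores)))
        return("scores must carry subject and task dimnames")
    TRUE
})

#' Ground truth of planted edge-ideology associations
#'
#' Describes which FC edges carry signal in the simulator: for a subject
#' with standardized ideology z, the latent correlation of edge (i, j) in
#' the given task is `baseCorr + effect * z`. Used to verify that every
#' downstream stage recovers known structure.
#'
#' @slot edges data.frame with columns task, roi_i, roi_j, effect
#'   (standardized slope of the edge correlation on ideology).
#' @slot baseCorr numeric baseline correlation of signal edges.
#' @slot noiseSd numeric scale of the BOLD noise.
#' @slot seed integer.
#' @seealso [plantedTruth()], [generateBoldTimeSeries()]
#' @export
setClass("PlantedTruth", representation(
    edges = "data.frame", baseCorr = "numeric", noiseSd = "numeric",
    seed = "integer"))

setValidity("PlantedTruth", function(object) {
    e <- object@edges
    need <- c("task", "roi_i", "roi_j", "effect")
    if (!all(need %in% names(e)))
        return("edges needs columns task, roi_i, roi_j, effect")
    if (nrow(e)) {
        if (any(e$roi_i >= e$roi_j))
            return("edges must satisfy roi_i < roi_j")
        key <- paste(e$task, e$roi_i, e$roi_j)
        if (anyDuplicated(key)) return("each (task, i, j) may be listed once")
    }
    if (object@noiseSd <= 0) return("noiseSd must be positive")
    TRUE
})

#' Gradient saliency summary for one task
#'
#' Dataset-mean gradient of the predicted ideology score with respect to
#' each input FC edge, its weighted degree centralities, the aggregation
#' to anatomical regions, and the top signed edges. Positive mean
#' gradients push predictions toward conservatism (ideology coded
#' 1 = Very liberal ... 6 = Very conservative), negative toward
#' liberalism.
#'
#' @slot taskId character.
#' @slot G numeric R x R mean edge-gradient matrix (zero diagonal).
#' @slot roiLabels integer original ROI indices for rows/columns of G.
#' @slot centrality numeric per-ROI weighted degree centrality.
#' @slot regionTable data.frame region, hemisphere, importance, flagged.
#' @slot topConservative,topLiberal integer length-2 ROI label pairs
#'   (NA when undefined).
#' @seealso [computeSaliency()]
#' @export
setClass("SaliencyResult", representation(
    taskId = "character", G = "matrix", roiLabels = "integer",
    centrality = "numeric", regionTable = "data.frame",
    topConservative = "integer", topLiberal = "integer"))

setValidity("SaliencyResult", function(object) {
    if (length(object@centrality) != nrow(object@G))
        return("centrality length must match G")
    if (any(object@centrality < 0)) return("centrality must be non-negative")
    TRUE
})

#' Principal component analysis of the score matrix
#'
#' @slot varianceFraction percent variance per component (sums to 100).
#' @slot contributions tasks x components percent contributions (each
#'   column sums to 100).
#' @slot scores subjects x components principal component scores.
#' @slot sdev component standard deviations.
#' @seealso [pcaScores()]
#' @export
setClass("PCAResult", representation(
    varianceFraction = "numeric", contributions = "matrix",
    scores = "matrix", sdev = "numeric"))

#' Monte Carlo cross-validation comparison of logistic models
#'
#' @slot auc,accuracy numeric matrices, samples x models.
#' @slot summary data.frame per model: mean/SD AUC, percentile 95% CI,
#'   mean accuracy.
#' @slot nSamples integer.
#' @slot seed integer.
#' @seealso [monteCarloCV()], [compareToBenchmark()]
#' @export
setClass("ComparisonResult", representation(
    auc = "matrix", accuracy = "matrix", summary = "data.frame",
    nSamples = "integer", seed = "integer"))
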