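#' Accessors for ideoconn classes
#'
#' Small accessor layer so user code never touches slots directly:
#' `cohortData()` returns the survey table, `ideology()` the 6-point
#' outcome, `subjectIds()` the identifiers, `fcValues()` the correlation
#' matrix of an [FCMatrix-class], `roiLabels()` the retained original ROI
#' indices, `scoreValues()` the subjects x tasks score matrix,
#' `foldAssignment()` the cross-validation fold per subject and
#' `taskIds()` the task names.
#'
#' @param object an ideoconn S4 object.
#' @return See details; vectors, matrices or data.frames as appropriate.
#' @name accessors
#' @aliases cohortData ideology subjectIds fcValues roiLabels scoreValues
#'   foldAssignment taskIds
NULL

#' @rdname accessors
#' @export
setGeneric("cohortData", function(object) standardGeneric("cohortData"))
#' @rdname accessors
#' @export
setGeneric("ideology", function(object) standardGeneric("ideology"))
#' @rdname accessors
#' @export
setGeneric("subjectIds", function(object) standardGeneric("subjectIds"))
#' @rdname accessors
#' @export
setGeneric("fcValues", function(object) standardGeneric("fcValues"))
#' @rdname accessors
#' @export
setGeneric("roiLabels", function(object) standardGeneric("roiLabels"))
#' @rdname accessors
#' @export
setGeneric("scoreValues", function(object) standardGeneric("scoreValues"))
#' @rdname accessors
#' @export
setGeneric("foldAssignment", function(object) standardGeneric("foldAssignment"))
#' @rdname accessors
#' @export
setGeneric("taskIds", function(object) standardGeneric("taskIds"))

#' @rdname accessors
#' @export
setMethod("cohortData", "Cohort", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("ideology", "Cohort", function(object) object@data$conservatism)
#' @rdname accessors
#' @export
setMethod("subjectIds", "Cohort", function(object) object@data$subject_id)
#' @rdname accessors
#' @export
setMethod("fcValues", "FCMatrix", function(object) object@E)
#' @rdname accessors
#' @export
setMethod("roiLabels", "FCMatrix", function(object) object@roiLabels)
#' @rdname accessors
#' @export
setMethod("roiLabels", "FCDataset", function(object) object@roiLabels)
#' @rdname accessors
#' @export
setMethod("subjectIds", "FCDataset", function(object) object@subjects)
#' @rdname accessors
#' @export
setMethod("taskIds", "FCDataset", function(object) object@tasks)
#' @rdname accessors
#' @export
setMethod("scoreValues", "IdeologyScoreMatrix", function(object) object@scores)
#' @rdname accessors
#' @export
setMethod("foldAssignment", "IdeologyScoreMatrix",
          function(object) object@foldAssignment)
#' @rdname accessors
#' @export
setMethod("subjectIds", "IdeologyScoreMatrix",
          function(object) rownames(object@scores))
#' @rdname accessors
#' @export
setMethod("taskIds", "IdeologyScoreMatrix",
          function(object) colnames(object@scores))

#' Retrieve an FC matrix for one subject and task
#'
#' @param object an [FCDataset-class].
#' @param subject,task identifiers.
#' @return An [FCMatrix-class].
#' @export
setGeneric("getFC", function(object, subject, task) standardGeneric("getFC"))

#' @rdname getFC
#' @export
setMethod("getFC", "FCDataset", function(object, subject, task) {
    key <- paste(subject, task, sep = ".")
    m <- object@matrices[[key]]
    if (is.null(m)) stop("no FC matrix for subject ", subject, ", task ", task)
    m
})

setMethod("show", "Cohort", function(object) {
    d <- object@data
    cat("Cohort with", nrow(d), "subjects\n")
    tab <- tabulate(d$conservatism, nbins = 6L)
    cat("  ideology (1=Very liberal .. 6=Very conservative):",
        paste(tab, collapse = "/"), "\n")
    cat("  covariates:", paste(setdiff(names(d), "subject_id"),
                               collapse = ", "), "\n")
})

setMethod("show", "RoiTimeSeries", function(object) {
    cat("RoiTimeSeries", object@subjectId, "/", object@taskId, ":",
        nrow(object@data), "timepoints x", ncol(object@data), "ROIs")
    if (length(object@missingRois))
        cat(" (missing ROI:", paste(object@missingRois, collapse = ","), ")")
    cat("\n")
})

setMethod("show", "FCMatrix", function(object) {
    cat("FCMatrix", object@subjectId, "/", object@taskId, ":",
        nrow(object@E), "x", ncol(object@E), "correlations\n")
})

setMethod("show", "FCDataset", function(object) {
    cat("FCDataset:", length(object@subjects), "subjects x",
        length(object@tasks), "tasks,", length(object@roiLabels),
        "retained ROIs\n")
})

setMethod("show", "IdeologyScoreMatrix", function(object) {
    cat("IdeologyScoreMatrix:", nrow(object@scores), "subjects x",
        ncol(object@scores), "tasks")
    if (length(object@foldAssignment))
        cat(",", max(object@foldAssignment), "folds")
    if (length(object@models)) cat(", fold models retained")
    cat("\n")
})

setMethod("show", "PlantedTruth", function(object) {
    cat("PlantedTruth:", nrow(object@edges), "signal edges, baseCorr =",
        object@baseCorr, ", noiseSd =", object@noiseSd, "\n")
})

setMethod("show", "SaliencyResult", function(object) {
    cat("SaliencyResult for task", object@taskId, ":", nrow(object@G),
        "ROIs,", nrow(object@regionTable), "regions\n")
    if (!anyNA(object@topConservative))
        cat("  top conservative edge: ROIs",
            paste(object@topConservative, collapse = "-"), "\n")
    if (!anyNA(object@topLiberal))
        cat("  top liberal edge: ROIs",
            paste(object@topLiberal, collapse = "-"), "\n")
})

setMethod("show", "PCAResult", function(object) {
    cat("PCAResult:", length(object@varianceFraction), "components;",
        "variance % =", paste(round(object@varianceFraction, 1),
                              collapse = ", "), "\n")
})

setMethod("show", "ComparisonResult", function(object) {
    cat("ComparisonResult over", object@nSamples, "Monte Carlo samples\n")
    print(object@summary, digits = 3)
})
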