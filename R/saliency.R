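#' Read an ROI-to-region atlas table
#'
#' Tab-delimited table with columns `roi` (original 1-based ROI index),
#' `region` (anatomical region label), `hemisphere` (`L`/`R`) and
#' `excluded` (0/1). Retained ROIs must map to exactly one region. The
#' packaged default is a synthetic stand-in grouping 269 ROIs (ROI 252
#' excluded) into 78 regions in the style of an AAL-derived parcellation;
#' substitute a real atlas table for anatomical interpretation.
#'
#' @param path file path; default is the packaged synthetic atlas.
#' @return data.frame atlas map.
#' @export
readAtlas <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "atlas_roi269_to_78regions_synthetic.tsv",
                            package = "ideoconn")
    atlas <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("roi", "region", "hemisphere", "excluded")
    if (!all(need %in% names(atlas)))
        stop("atlas needs columns ", paste(need, collapse = ", "))
    kept <- atlas[atlas$excluded == 0, ]
    if (anyDuplicated(kept$roi)) stop("retained ROI mapped more than once")
    atlas
}

#' Dataset-mean gradient of the score with respect to input edges
#'
#' For every subject, computes the evaluation-mode gradient of that
#' subject's own out-of-fold model's predicted score with respect to each
#' input edge of the subject's FC matrix (dropout off), then averages the
#' gradient matrices over the dataset. Using each subject's held-out
#' model keeps the saliency map free of data leakage; a pooled variant
#' averaging predictions over all fold models is available.
#'
#' @param scores an [IdeologyScoreMatrix-class] holding fold models
#'   (`keepModels = TRUE` in [crossValidatedScores()]).
#' @param dataset the [FCDataset-class] the scores were computed from.
#' @param task task identifier.
#' @param gradientModel `"oof"` (each subject's out-of-fold model) or
#'   `"pooled"` (mean gradient over all fold models).
#' @return R x R mean gradient matrix with zero diagonal.
#' @export
edgeGradients <- function(scores, dataset, task,
                          gradientModel = c("oof", "pooled")) {
    gradientModel <- match.arg(gradientModel)
    stopifnot(is(scores, "IdeologyScoreMatrix"), is(dataset, "FCDataset"))
    if (!task %in% taskIds(dataset)) stop("unknown task ", task)
    mods <- scores@models[[task]]
    if (is.null(mods) || !length(mods))
        stop("no fold models stored for task ", task,
             "; rerun crossValidatedScores with keepModels = TRUE")
    ids <- subjectIds(scores)
    folds <- foldAssignment(scores)
    R <- length(roiLabels(dataset))
    G <- matrix(0, R, R)
    for (k in seq_along(ids)) {
        E <- fcValues(getFC(dataset, ids[k], task))
        if (gradientModel == "oof") {
            m <- mods[[folds[k]]]
            if (is.null(m)) stop("missing fold model for fold ", folds[k])
            G <- G + .inputGradient(E, m$params, m$config)
        } else {
            for (m in mods)
                G <- G + .inputGradient(E, m$params, m$config) / length(mods)
        }
    }
    G <- G / length(ids)
    diag(G) <- 0
    G
}

#' Weighted degree centrality of a gradient map
#'
#' `centrality(i) = sum_j |G(i, j)|`: the summed magnitude of the mean
#' edge gradients incident to ROI i, measuring how strongly that region's
#' connections drive the prediction.
#'
#' @param G square gradient matrix.
#' @return Non-negative numeric vector, one value per ROI.
#' @export
nodeCentrality <- function(G) {
    G <- as.matrix(G)
    if (nrow(G) != ncol(G)) stop("G must be square")
    rowSums(abs(G))
}

#' Aggregate ROI centralities to anatomical regions
#'
#' Region importance is the mean centrality of its member ROIs. A region
#' is flagged as influential when its importance exceeds the
#' across-region mean by `flagSd` standard deviations (default 1.645, a
#' one-sided 95% rule).
#'
#' @param centrality numeric per-ROI centralities.
#' @param roiLabels original ROI indices corresponding to `centrality`.
#' @param atlas atlas table from [readAtlas()]; must cover all retained
#'   ROIs.
#' @param flagSd flagging threshold in across-region SD units.
#' @return data.frame region, hemisphere, importance, flagged, sorted by
#'   decreasing importance.
#' @export
aggregateToRegions <- function(centrality, roiLabels, atlas = readAtlas(),
                               flagSd = 1.645) {
    stopifnot(length(centrality) == length(roiLabels))
    kept <- atlas[atlas$excluded == 0, ]
    idx <- match(roiLabels, kept$roi)
    if (anyNA(idx))
        stop("atlas does not map ROIs: ",
             paste(roiLabels[is.na(idx)], collapse = ", "))
    key <- paste(kept$region[idx], kept$hemisphere[idx], sep = "|")
    imp <- tapply(centrality, key, mean)
    parts <- strsplit(names(imp), "|", fixed = TRUE)
    out <- data.frame(
        region = vapply(parts, `[`, character(1), 1L),
        hemisphere = vapply(parts, `[`, character(1), 2L),
        importance = as.numeric(imp), row.names = NULL)
    thr <- mean(out$importance) + flagSd * stats::sd(out$importance)
    out$flagged <- out$importance > thr
    out[order(-out$importance), , drop = FALSE]
}

#' Most liberal- and conservative-predictive edges
#'
#' The gradient map is symmetrized (`(G + t(G)) / 2`; the two
#' orientations of a symmetric input are not separately identifiable)
#' and searched over `i < j`. The conservative edge is the argmax (most
#' positive mean gradient: higher score = more conservative under the
#' 1-6 coding) and the liberal edge the argmin (most negative). Ties
#' break to the lexicographically smallest (i, j); a side with no
#' strictly signed entry is returned as `NA` with a warning.
#'
#' @param G square gradient matrix.
#' @param roiLabels optional original ROI indices used to label the
#'   returned pairs.
#' @return List with integer pairs `conservative` and `liberal`.
#' @export
topSignedEdges <- function(G, roiLabels = NULL) {
    G <- as.matrix(G)
    if (all(G == 0)) stop("gradient map is identically zero")
    Gs <- (G + t(G)) / 2
    R <- nrow(Gs)
    if (is.null(roiLabels)) roiLabels <- seq_len(R)
    ut <- upper.tri(Gs)
    vals <- Gs[ut]
    ij <- which(ut, arr.ind = TRUE)          # row-major over columns: i < j
    ord <- order(ij[, 1], ij[, 2])
    vals <- vals[ord]; ij <- ij[ord, , drop = FALSE]
    pick <- function(v) as.integer(roiLabels[ij[v, ]])
    conservative <- if (any(vals > 0)) pick(which.max(vals)) else {
        warning("no positive mean gradient; conservative edge undefined")
        c(NA_integer_, NA_integer_)
    }
    liberal <- if (any(vals < 0)) pick(which.min(vals)) else {
        warning("no negative mean gradient; liberal edge undefined")
        c(NA_integer_, NA_integer_)
    }
    list(conservative = conservative, liberal = liberal)
}

#' Full saliency analysis for one task
#'
#' Chains [edgeGradients()], [nodeCentrality()], [aggregateToRegions()]
#' and [topSignedEdges()] into a [SaliencyResult-class].
#'
#' @inheritParams edgeGradients
#' @param atlas atlas table from [readAtlas()].
#' @param flagSd flagging threshold passed to [aggregateToRegions()].
#' @return A [SaliencyResult-class].
#' @export
computeSaliency <- function(scores, dataset, task, atlas = readAtlas(),
                            flagSd = 1.645,
                            gradientModel = c("oof", "pooled")) {
    G <- edgeGradients(scores, dataset, task, gradientModel)
    cen <- nodeCentrality(G)
    labs <- roiLabels(dataset)
    regions <- aggregateToRegions(cen, labs, atlas, flagSd)
    top <- topSignedEdges(G, labs)
    new("SaliencyResult", taskId = task, G = G, roiLabels = labs,
        centrality = cen, regionTable = regions,
        topConservative = top$conservative, topLiberal = top$liberal)
}
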