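#' Stratify subjects into extreme and moderate ideology subgroups
#'
#' Extreme = Very liberal (1) or Very conservative (6); moderate =
#' somewhat liberal, liberal, conservative and somewhat conservative
#' (2-5). The labels partition the cohort.
#'
#' @param cohort a [Cohort-class].
#' @return Character vector of `"extreme"`/`"moderate"` per subject.
#' @export
stratifyIdeology <- function(cohort) {
    y <- ideology(cohort)
    if (any(y < 1L | y > 6L)) stop("ideology outside 1..6")
    ifelse(y %in% c(1L, 6L), "extreme", "moderate")
}

# p-value of a Pearson correlation; "t" is the exact t-distribution test,
# "chisq" the score-type variant p = P(chi^2_1 > n r^2).
.corPValue <- function(r, n, method = c("t", "chisq")) {
    method <- match.arg(method)
    if (method == "t") {
        tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
        2 * stats::pt(-abs(tt), df = n - 2)
    } else {
        stats::pchisq(n * r^2, df = 1, lower.tail = FALSE)
    }
}

#' Correlate out-of-fold scores with true ideology
#'
#' Pearson correlation of each task's score column with the 6-point
#' ideology over the requested subgroup, with a two-sided p-value and a
#' Bonferroni correction `p_bonferroni = min(1, mTests * p_raw)` for the
#' family of simultaneous task tests.
#'
#' @param scores an [IdeologyScoreMatrix-class].
#' @param cohort a [Cohort-class] (subjects matched by identifier).
#' @param subgroup `"overall"`, `"moderate"` or `"extreme"`.
#' @param mTests number of simultaneous tests (default: one per task).
#' @param method `"t"` for the exact correlation t-test (default) or
#'   `"chisq"` for the chi-squared score variant.
#' @return data.frame with columns task, subgroup, n, r, p_raw,
#'   p_bonferroni.
#' @export
correlateScores <- function(scores, cohort, subgroup = "overall",
                            mTests = ncol(scoreValues(scores)),
                            method = c("t", "chisq")) {
    stopifnot(is(scores, "IdeologyScoreMatrix"), is(cohort, "Cohort"))
    method <- match.arg(method)
    subgroup <- match.arg(subgroup, c("overall", "moderate", "extreme"))
    S <- scoreValues(scores)
    ord <- match(rownames(S), subjectIds(cohort))
    if (anyNA(ord)) stop("score subjects missing from cohort")
    y <- ideology(cohort)[ord]
    lab <- stratifyIdeology(cohort)[ord]
    keep <- if (subgroup == "overall") seq_along(y)
            else which(lab == subgroup)
    if (length(keep) < 3L) stop("fewer than 3 subjects in subgroup")
    ys <- y[keep]
    if (stats::sd(ys) == 0) stop("ideology has zero variance in subgroup")
    r <- apply(S[keep, , drop = FALSE], 2, function(col) {
        if (stats::sd(col) == 0) stop("zero-variance score column")
        stats::cor(col, ys)
    })
    p <- .corPValue(r, length(keep), method)
    data.frame(task = colnames(S), subgroup = subgroup, n = length(keep),
               r = unname(r), p_raw = unname(p),
               p_bonferroni = pmin(1, mTests * unname(p)),
               row.names = NULL)
}

#' Pairwise correlations between the tasks' score columns
#'
#' @inheritParams correlateScores
#' @return Symmetric tasks x tasks correlation matrix with unit diagonal.
#' @export
pairwiseScoreCorrelations <- function(scores, cohort, subgroup = "overall") {
    stopifnot(is(scores, "IdeologyScoreMatrix"), is(cohort, "Cohort"))
    subgroup <- match.arg(subgroup, c("overall", "moderate", "extreme"))
    S <- scoreValues(scores)
    ord <- match(rownames(S), subjectIds(cohort))
    if (anyNA(ord)) stop("score subjects missing from cohort")
    lab <- stratifyIdeology(cohort)[ord]
    keep <- if (subgroup == "overall") seq_len(nrow(S))
            else which(lab == subgroup)
    if (length(keep) < 3L) stop("fewer than 3 subjects in subgroup")
    C <- stats::cor(S[keep, , drop = FALSE])
    (C + t(C)) / 2
}

#' Principal component analysis of the score matrix
#'
#' PCA of the subjects x tasks score matrix with columns centered and
#' (by default) scaled to unit variance. The contribution of task j to
#' component m is `100 * loading_{jm}^2 / sum_j loading_{jm}^2`, so each
#' component's contributions sum to 100%.
#'
#' @param scores an [IdeologyScoreMatrix-class] (requires more subjects
#'   than tasks).
#' @param scale. scale columns to unit variance before decomposition.
#' @return A [PCAResult-class].
#' @export
pcaScores <- function(scores, scale. = TRUE) {
    stopifnot(is(scores, "IdeologyScoreMatrix"))
    S <- scoreValues(scores)
    if (nrow(S) <= ncol(S)) stop("need more subjects than tasks")
    if (any(apply(S, 2, stats::sd) == 0)) stop("zero-variance score column")
    pc <- stats::prcomp(S, center = TRUE, scale. = scale.)
    varfrac <- 100 * pc$sdev^2 / sum(pc$sdev^2)
    contrib <- 100 * sweep(pc$rotation^2, 2, colSums(pc$rotation^2), `/`)
    new("PCAResult", varianceFraction = varfrac, contributions = contrib,
        scores = pc$x, sdev = pc$sdev)
}
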