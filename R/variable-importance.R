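#' L1-penalized variable importance
#'
#' Fits a LASSO logistic regression of the binary ideology labels on all
#' predictors, with features standardized to unit variance so absolute
#' coefficients are comparable across scales. The penalty is chosen by
#' k-fold cross-validated binomial deviance over glmnet's geometric
#' penalty path (minimum-deviance rule by default; one-standard-error
#' rule optional). Importance is the absolute standardized coefficient at
#' the chosen penalty; variables shrunk to zero are dropped.
#'
#' @param features data.frame of predictors (see [assembleFeatures()]).
#' @param labels binary 0/1 vector.
#' @param predictors columns of `features` to consider (default: all).
#' @param nFolds cross-validation folds for the penalty choice.
#' @param seed integer seed (controls fold assignment).
#' @param rule `"min"` (minimum CV deviance) or `"1se"`.
#' @return data.frame with columns variable, importance, sorted in
#'   strictly decreasing importance; zero rows (with a warning) when the
#'   penalty removes everything.
#' @export
lassoImportance <- function(features, labels, predictors = names(features),
                            nFolds = 10L, seed = 1L,
                            rule = c("min", "1se")) {
    rule <- match.arg(rule)
    if (length(unique(labels)) < 2L) stop("labels contain a single class")
    X <- as.matrix(features[, predictors, drop = FALSE])
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) stop("zero-variance predictor: ",
                            paste(predictors[sds == 0], collapse = ", "))
    Xs <- scale(X)
    set.seed(.deriveSeed(seed, 37L))
    foldid <- sample(rep_len(seq_len(nFolds), length(labels)))
    cv <- glmnet::cv.glmnet(Xs, labels, family = "binomial", alpha = 1,
                            foldid = foldid, standardize = FALSE)
    lam <- if (rule == "min") cv$lambda.min else cv$lambda.1se
    beta <- drop(as.matrix(stats::coef(cv$glmnet.fit, s = lam)))[-1]
    keep <- which(beta != 0)
    if (!length(keep)) {
        warning("all coefficients shrunk to zero at the chosen penalty")
        return(data.frame(variable = character(0), importance = numeric(0)))
    }
    out <- data.frame(variable = names(beta)[keep],
                      importance = abs(beta[keep]), row.names = NULL)
    out[order(-out$importance), , drop = FALSE]
}

#' Refit selected variables by unpenalized logistic regression
#'
#' Maximum-likelihood logistic fit on the selected predictors (raw
#' scale), with Wald standard errors and two-sided p-values, as reported
#' alongside LASSO importances. Separation is flagged via the fallback in
#' [fitLogistic()]; in that case standard errors are unavailable.
#'
#' @param features data.frame of predictors.
#' @param labels binary 0/1 vector.
#' @param selected non-empty character vector of selected variables.
#' @return data.frame with columns variable, coefficient, se, p_value.
#' @export
refitSelected <- function(features, labels, selected) {
    if (!length(selected)) stop("selection is empty; nothing to refit")
    fit <- fitLogistic(features, labels, selected)
    if (fit$type != "glm") {
        warning("separation detected; reporting ridge coefficients ",
                "without standard errors")
        cf <- coef(fit)
        cf <- cf[setdiff(names(cf), c("(Intercept)", ".pad"))]
        return(data.frame(variable = names(cf), coefficient = unname(cf),
                          se = NA_real_, p_value = NA_real_,
                          row.names = NULL))
    }
    sm <- summary(fit$fit)$coefficients
    sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
    data.frame(variable = rownames(sm), coefficient = sm[, "Estimate"],
               se = sm[, "Std. Error"], p_value = sm[, "Pr(>|z|)"],
               row.names = NULL)
}

#' Combined importance table
#'
#' Runs [lassoImportance()] and augments the surviving variables with the
#' unpenalized refit coefficients, standard errors and p-values from
#' [refitSelected()], in decreasing order of importance.
#'
#' @inheritParams lassoImportance
#' @return data.frame: variable, importance, coefficient, se, p_value.
#' @export
variableImportance <- function(features, labels,
                               predictors = names(features), nFolds = 10L,
                               seed = 1L, rule = c("min", "1se")) {
    imp <- lassoImportance(features, labels, predictors, nFolds, seed, rule)
    if (!nrow(imp))
        return(cbind(imp, coefficient = numeric(0), se = numeric(0),
                     p_value = numeric(0)))
    refit <- refitSelected(features, labels, imp$variable)
    merge(imp, refit, by = "variable", sort = FALSE)
}
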