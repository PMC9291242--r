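#' Very leaky rectified linear activation
#'
#' Elementwise `f(x) = x` for `x >= 0` and `x/3` for `x < 0`, the
#' activation used throughout the connectome network.
#'
#' @param x numeric vector, matrix or array.
#' @return Object of the same shape.
#' @examples
#' vleakyRelu(c(-3, 0, 3))  # -1 0 3
#' @export
vleakyRelu <- function(x) ifelse(x < 0, x / 3, x)

# derivative of vleakyRelu (subgradient 1 at 0)
.dvleaky <- function(x) ifelse(x < 0, 1 / 3, 1)

#' Edge-to-node layer forward pass
#'
#' Cross-shaped convolution mapping an R x R connectivity matrix to R node
#' features: `out(i, f) = sum_j rowWeights(f, j) E(i, j) +
#' colWeights(f, j) E(j, i) + bias(f)`, before activation. Each filter
#' scans the row and column incident to every node.
#'
#' @param E numeric R x R matrix.
#' @param rowWeights,colWeights numeric F x R weight matrices.
#' @param bias numeric length-F vector.
#' @return R x F matrix of node features.
#' @export
e2nForward <- function(E, rowWeights, colWeights, bias) {
    E <- as.matrix(E)
    if (ncol(rowWeights) != nrow(E) || !identical(dim(rowWeights),
                                                  dim(colWeights)))
        stop("weight shapes inconsistent with E")
    if (length(bias) != nrow(rowWeights)) stop("bias length must equal filters")
    H <- E %*% t(rowWeights) + t(E) %*% t(colWeights)
    sweep(H, 2, bias, `+`)
}

#' Node-to-graph layer forward pass
#'
#' Collapses R x F node features to G graph-level units by full weighted
#' summation: `out(m) = sum_i sum_f weights(m, i, f) H(i, f) + bias(m)`,
#' before activation.
#'
#' @param H numeric R x F node-feature matrix.
#' @param weights numeric G x R x F array.
#' @param bias numeric length-G vector.
#' @return Numeric length-G vector.
#' @export
n2gForward <- function(H, weights, bias) {
    dw <- dim(weights)
    if (length(dw) != 3L || dw[2] != nrow(H) || dw[3] != ncol(H))
        stop("weights must be a G x R x F array matching H")
    if (length(bias) != dw[1]) stop("bias length must equal units")
    W <- matrix(weights, nrow = dw[1])      # G x (R*F), (i, f) column-major
    drop(W %*% as.vector(H)) + bias
}

# ---- internal batched network core -----------------------------------------
#
# Parameters are stored in the batched parameterization:
#   A  (R x F)  = t(rowWeights);  B (R x F) = t(colWeights);  b1 (F)
#   W  (G x R*F) N2G weights;     b2 (G)
#   w3 (G) output weights;        b3 scalar
#   bnMean, bnSd (R x R) training-set normalization for evaluation mode
# Data are R x R x n arrays of FC matrices.

.initParams <- function(R, config) {
    Fc <- config$nE2nFilters; G <- config$nN2gUnits
    list(A = matrix(stats::rnorm(R * Fc, 0, 1 / sqrt(2 * R)), R, Fc),
         B = matrix(stats::rnorm(R * Fc, 0, 1 / sqrt(2 * R)), R, Fc),
         b1 = numeric(Fc),
         W = matrix(stats::rnorm(G * R * Fc, 0, 1 / sqrt(R * Fc)), G, R * Fc),
         b2 = numeric(G),
         w3 = stats::rnorm(G, 0, 1 / sqrt(G)),
         b3 = 0,
         bnMean = NULL, bnSd = NULL)
}

# stack an (R, R, b) array into (R*b, R) with row index (i, s)
.stackRows <- function(arr) {
    d <- dim(arr)
    matrix(aperm(arr, c(1, 3, 2)), nrow = d[1] * d[3])
}
.stackRowsT <- function(arr) {
    d <- dim(arr)
    matrix(aperm(arr, c(2, 3, 1)), nrow = d[1] * d[3])
}

.batchNormStats <- function(arr) {
    m <- rowMeans(arr, dims = 2)
    v <- rowMeans(arr^2, dims = 2) - m^2
    list(mean = m, sd = pmax(sqrt(pmax(v, 0)), 1e-3))
}

# Forward pass on a batch. `training` switches batch-statistic
# normalization and dropout on; evaluation mode uses the stored
# training-set statistics and is deterministic.
.nnForward <- function(arr, params, config, training = FALSE,
                       cache = FALSE) {
    d <- dim(arr); R <- d[1]; b <- d[3]
    Fc <- config$nE2nFilters; G <- config$nN2gUnits
    if (training) {
        bn <- .batchNormStats(arr)
    } else {
        if (is.null(params$bnMean))
            bn <- list(mean = matrix(0, R, R), sd = matrix(1, R, R))
        else bn <- list(mean = params$bnMean, sd = params$bnSd)
    }
    En <- (arr - as.vector(bn$mean)) / as.vector(bn$sd)
    dim(En) <- d
    bigE <- .stackRows(En)
    bigEt <- .stackRowsT(En)
    Hpre <- bigE %*% params$A + bigEt %*% params$B
    Hpre <- Hpre + rep(params$b1, each = nrow(Hpre))
    H <- vleakyRelu(Hpre)
    Hmat <- matrix(aperm(array(H, c(R, b, Fc)), c(2, 1, 3)), nrow = b)
    Gpre <- Hmat %*% t(params$W)
    Gpre <- Gpre + rep(params$b2, each = b)
    Ga <- vleakyRelu(Gpre)
    if (training && config$dropoutRate > 0) {
        keep <- 1 - config$dropoutRate
        mask <- matrix(stats::runif(b * G) < keep, b, G)
        D <- Ga * mask / keep
    } else {
        mask <- NULL
        D <- Ga
    }
    score <- drop(D %*% params$w3) + params$b3
    if (!cache) return(score)
    list(score = score, En = En, bigE = bigE, bigEt = bigEt,
         Hpre = Hpre, Hmat = Hmat, Gpre = Gpre, D = D, mask = mask,
         bn = bn, R = R, b = b, Fc = Fc, G = G)
}

# Backward pass for mean squared (Euclidean) loss; returns parameter
# gradients in the same layout as the parameter list.
.nnBackward <- function(cc, params, config, y) {
    b <- cc$b; R <- cc$R; Fc <- cc$Fc; G <- cc$G
    ds <- 2 * (cc$score - y) / b
    gw3 <- drop(crossprod(cc$D, ds))
    gb3 <- sum(ds)
    dD <- tcrossprod(ds, params$w3)                     # b x G
    dGa <- if (!is.null(cc$mask))
        dD * cc$mask / (1 - config$dropoutRate) else dD
    dGpre <- dGa * .dvleaky(cc$Gpre)
    gW <- crossprod(dGpre, cc$Hmat)                     # G x R*F
    gb2 <- colSums(dGpre)
    dHmat <- dGpre %*% params$W                         # b x R*F
    dHbig <- matrix(aperm(array(dHmat, c(b, R, Fc)), c(2, 1, 3)),
                    nrow = R * b)
    dHpre <- dHbig * .dvleaky(cc$Hpre)
    gA <- crossprod(cc$bigE, dHpre)
    gB <- crossprod(cc$bigEt, dHpre)
    gb1 <- colSums(dHpre)
    list(A = gA, B = gB, b1 = gb1, W = gW, b2 = gb2, w3 = gw3, b3 = gb3)
}

# Gradient of the evaluation-mode score with respect to every raw input
# edge, for a single matrix E (R x R). The affine normalization Jacobian
# (1/sd per edge) is folded in so the map refers to raw correlations.
.inputGradient <- function(E, params, config) {
    R <- nrow(E)
    arr <- array(E, c(R, R, 1L))
    cc <- .nnForward(arr, params, config, training = FALSE, cache = TRUE)
    dGpre <- params$w3 * .dvleaky(drop(cc$Gpre))        # G
    dHmat <- drop(matrix(dGpre, 1) %*% params$W)        # R*F
    dHbig <- matrix(dHmat, nrow = R)                    # R x F (b = 1)
    dHpre <- dHbig * .dvleaky(matrix(cc$Hpre, nrow = R))
    dE <- tcrossprod(dHpre, params$A) + t(tcrossprod(dHpre, params$B))
    dE / cc$bn$sd
}

#' Forward pass of the connectome regression network
#'
#' Pipeline: per-edge input normalization, edge-to-node layer, very leaky
#' ReLU, node-to-graph layer, very leaky ReLU, dropout (training mode
#' only), linear output unit. In evaluation mode the normalization uses
#' the statistics stored at training time and the output is a
#' deterministic function of the input.
#'
#' @param E an [FCMatrix-class] or plain R x R matrix.
#' @param params parameter list as produced by [trainNetwork()].
#' @param config a [networkConfig()].
#' @param training logical; enables dropout and batch-statistic
#'   normalization (single-matrix calls in training mode fall back to the
#'   stored statistics).
#' @return Scalar predicted score.
#' @export
modelForward <- function(E, params, config, training = FALSE) {
    if (is(E, "FCMatrix")) E <- fcValues(E)
    E <- as.matrix(E)
    R <- nrow(E)
    arr <- array(E, c(R, R, 1L))
    if (training && config$dropoutRate > 0) {
        # single-sample batch statistics are degenerate; normalize with the
        # stored statistics but still apply dropout after the N2G activation
        cc <- .nnForward(arr, params, config, training = FALSE, cache = TRUE)
        keep <- 1 - config$dropoutRate
        mask <- stats::runif(length(params$w3)) < keep
        drop(sum(drop(cc$D) * mask / keep * params$w3)) + params$b3
    } else {
        .nnForward(arr, params, config, training = FALSE)
    }
}

#' Gradient of the predicted score with respect to input edges
#'
#' Evaluation-mode partial derivatives of [modelForward()] with respect to
#' every entry of the input FC matrix, with the input-normalization
#' Jacobian folded in (gradients refer to raw correlations).
#'
#' @inheritParams modelForward
#' @return R x R numeric gradient matrix.
#' @export
modelEdgeGradient <- function(E, params, config) {
    if (is(E, "FCMatrix")) E <- fcValues(E)
    .inputGradient(as.matrix(E), params, config)
}
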