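test_that("edge gradients of a linear model recover its coefficients", {
    set.seed(40)
    R <- 8
    s <- rnorm(R); r <- rnorm(R)
    lp <- linearParams(s, r)
    E <- randomFC(R)
    G <- modelEdgeGradient(E, lp, linearConfig())
    expect_equal(G, outer(s, r), tolerance = 1e-10)
    # constant-output model has zero gradients everywhere
    z <- lp
    for (nm in c("A", "B", "W", "w3")) z[[nm]] <- z[[nm]] * 0
    expect_equal(modelEdgeGradient(E, z, linearConfig()),
                 matrix(0, R, R))
})

test_that("gradients agree with finite differences on random 10-ROI models", {
    set.seed(41)
    for (rep in 1:3) {
        mats <- lapply(1:12, function(i) randomFC(10))
        fit <- trainNetwork(mats, rnorm(12, 3),
                            networkConfig(nE2nFilters = 4L, nN2gUnits = 3L,
                                          nEpochs = 4L), seed = rep)
        E <- mats[[sample(12, 1)]]
        g <- modelEdgeGradient(E, fit$params, fit$config)
        h <- 1e-5
        fd <- matrix(0, 10, 10)
        for (i in 1:10) for (j in 1:10) {
            Ep <- E; Em <- E
            Ep[i, j] <- Ep[i, j] + h; Em[i, j] <- Em[i, j] - h
            fd[i, j] <- (modelForward(Ep, fit$params, fit$config) -
                         modelForward(Em, fit$params, fit$config)) / (2 * h)
        }
        off <- !diag(TRUE, 10)
        expect_lt(max(abs(g - fd)[off]) / max(abs(fd[off])), 1e-4)
    }
})

test_that("node centrality sums absolute gradients and is equivariant", {
    G0 <- matrix(0, 5, 5)
    expect_equal(nodeCentrality(G0), rep(0, 5))
    G1 <- G0; G1[3, 5] <- -2.5
    expect_equal(nodeCentrality(G1), c(0, 0, 2.5, 0, 0))
    set.seed(42)
    G <- matrix(rnorm(49), 7, 7)
    oracle <- sapply(1:7, function(i) sum(abs(G[i, ])))
    expect_equal(nodeCentrality(G), oracle)
    # permutation equivariance
    p <- sample(7)
    expect_equal(nodeCentrality(G[p, p]), nodeCentrality(G)[p])
})

test_that("region aggregation averages member ROIs and flags outliers", {
    nRegion <- 12
    atlas <- data.frame(
        roi = 1:37,
        region = c(rep(LETTERS[1:nRegion], each = 3), "X"),
        hemisphere = rep("L", 37),
        excluded = c(rep(0L, 36), 1L))
    cen <- rep(1, 36)
    out <- aggregateToRegions(cen, 1:36, atlas)
    expect_true(all(abs(out$importance - 1) < 1e-12))
    expect_false(any(out$flagged))
    # one region far above an otherwise flat baseline: only it is flagged
    cen2 <- rep(1, 36); cen2[4:6] <- 10
    out2 <- aggregateToRegions(cen2, 1:36, atlas)
    expect_identical(out2$region[out2$flagged], "B")
    # group-by oracle on random centralities
    set.seed(43)
    cen3 <- runif(36)
    out3 <- aggregateToRegions(cen3, 1:36, atlas)
    oracle <- tapply(cen3, atlas$region[1:36], mean)
    for (i in seq_len(nrow(out3)))
        expect_equal(out3$importance[i], unname(oracle[out3$region[i]]))
    expect_error(aggregateToRegions(rep(1, 37), 1:37, atlas), "does not map")
})

test_that("packaged atlas maps 268 retained ROIs onto 78 regions", {
    atlas <- readAtlas()
    expect_identical(nrow(atlas), 269L)
    expect_identical(atlas$roi[atlas$excluded == 1], 252L)
    kept <- atlas[atlas$excluded == 0, ]
    expect_identical(nrow(kept), 268L)
    expect_identical(length(unique(paste(kept$region, kept$hemisphere))), 78L)
})

test_that("top signed edges follow sign conventions and tie-breaks", {
    G <- matrix(0, 6, 6)
    G[2, 4] <- G[4, 2] <- 0.9
    G[1, 5] <- G[5, 1] <- -0.7
    top <- topSignedEdges(G)
    expect_identical(top$conservative, c(2L, 4L))
    expect_identical(top$liberal, c(1L, 5L))
    # sign flip swaps the two roles
    topF <- topSignedEdges(-G)
    expect_identical(topF$conservative, c(1L, 5L))
    expect_identical(topF$liberal, c(2L, 4L))
    # single positive entry: liberal side undefined, flagged
    Gp <- matrix(0, 4, 4); Gp[1, 2] <- Gp[2, 1] <- 0.5
    expect_warning(topP <- topSignedEdges(Gp), "liberal edge undefined")
    expect_identical(topP$conservative, c(1L, 2L))
    expect_true(anyNA(topP$liberal))
    expect_error(topSignedEdges(matrix(0, 3, 3)), "identically zero")
    # ties break to the lexicographically smallest pair
    Gt <- matrix(0, 4, 4)
    Gt[1, 3] <- Gt[3, 1] <- 0.5
    Gt[1, 2] <- Gt[2, 1] <- 0.5
    Gt[2, 4] <- Gt[4, 2] <- -0.5
    Gt[1, 4] <- Gt[4, 1] <- -0.5
    topT <- topSignedEdges(Gt)
    expect_identical(topT$conservative, c(1L, 2L))
    expect_identical(topT$liberal, c(1L, 4L))
})

test_that("planted-edge saliency recovers endpoints and signs end to end", {
    w <- plantedWorld(3, nSubjects = 120, nRois = 24, tasks = "task1")
    cv <- crossValidatedScores(w$dataset, w$cohort, k = 5,
                               space = quickSpace(nEpochs = 25L), seed = 3)
    G <- edgeGradients(cv, w$dataset, "task1")
    expect_identical(dim(G), c(24L, 24L))
    expect_identical(unique(diag(G)), 0)
    top <- topSignedEdges(G, roiLabels(w$dataset))
    expect_identical(sort(top$conservative), c(3L, 7L))
    expect_identical(sort(top$liberal), c(12L, 20L))
    # planted endpoints occupy the top centralities
    cen <- nodeCentrality(G)
    expect_true(all(c(3, 7, 12, 20) %in%
                    roiLabels(w$dataset)[order(-cen)[1:5]]))
    # pooled-model variant produces a gradient map of the same shape
    Gp <- edgeGradients(cv, w$dataset, "task1", gradientModel = "pooled")
    expect_identical(dim(Gp), dim(G))
    expect_error(edgeGradients(cv, w$dataset, "nope"), "unknown task")
})
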