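#' Write and read a cohort as tab-delimited text
#'
#' @param cohort a [Cohort-class].
#' @param path output file.
#' @return `writeCohort` returns `path` invisibly; `readCohort` a
#'   validated [Cohort-class] (errors name the offending row).
#' @export
writeCohort <- function(cohort, path) {
    stopifnot(is(cohort, "Cohort"))
    utils::write.table(cohortData(cohort), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    missing_cols <- setdiff(.COHORT_COLS, names(d))
    if (length(missing_cols))
        stop("cohort file missing columns: ",
             paste(missing_cols, collapse = ", "))
    for (col in c(.LIKERT5, .LIKERT6)) {
        hi <- if (col %in% .LIKERT5) 5L else 6L
        bad <- which(is.na(d[[col]]) | d[[col]] < 1 | d[[col]] > hi |
                     d[[col]] != round(d[[col]]))
        if (length(bad))
            stop("column ", col, " out of range 1..", hi, " in row ",
                 bad[1])
    }
    dup <- which(duplicated(d$subject_id))
    if (length(dup)) stop("duplicate subject_id in row ", dup[1])
    message("read cohort with ", nrow(d), " subjects")
    new("Cohort", data = d[, .COHORT_COLS])
}

#' Write ROI time series as delimited text, one file per subject-task
#'
#' Files are named `<subject>_<task>.tsv`; missing ROIs are written as
#' `NA` markers, never zeros.
#'
#' @param series named list of [RoiTimeSeries-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
writeTimeSeries <- function(series, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(series, function(s) {
        p <- file.path(dir, paste0(s@subjectId, "_", s@taskId, ".tsv"))
        utils::write.table(s@data, p, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
        p
    }, character(1))
    invisible(paths)
}

#' Read ROI time series written by [writeTimeSeries()]
#'
#' @param dir directory of `<subject>_<task>.tsv` files.
#' @return Named list of [RoiTimeSeries-class].
#' @export
readTimeSeries <- function(dir) {
    files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
    if (!length(files)) stop("no .tsv files in ", dir)
    out <- lapply(files, function(p) {
        base <- sub("\\.tsv$", "", basename(p))
        parts <- strsplit(base, "_")[[1]]
        if (length(parts) < 2L) stop("cannot parse subject/task from ", p)
        task <- parts[length(parts)]
        subject <- paste(parts[-length(parts)], collapse = "_")
        X <- as.matrix(utils::read.table(p, sep = "\t"))
        dimnames(X) <- NULL
        miss <- which(colSums(is.na(X)) == nrow(X))
        new("RoiTimeSeries", subjectId = subject, taskId = task,
            data = X, missingRois = as.integer(miss))
    })
    names(out) <- vapply(out, function(s)
        paste(s@subjectId, s@taskId, sep = "."), character(1))
    out
}

#' Write planted ground truth as a human-readable key-value file
#'
#' @param truth a [PlantedTruth-class].
#' @param path output file.
#' @return `path` invisibly; `readPlantedTruth` the parsed object.
#' @export
writePlantedTruth <- function(truth, path) {
    stopifnot(is(truth, "PlantedTruth"))
    lines <- c(paste0("baseCorr: ", format(truth@baseCorr, digits = 17)),
               paste0("noiseSd: ", format(truth@noiseSd, digits = 17)),
               paste0("seed: ", truth@seed))
    e <- truth@edges
    if (nrow(e))
        lines <- c(lines, paste0("edge: ", e$task, " ", e$roi_i, " ",
                                 e$roi_j, " ", format(e$effect, digits = 17)))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writePlantedTruth
#' @export
readPlantedTruth <- function(path) {
    lines <- readLines(path)
    getv <- function(key) {
        ln <- grep(paste0("^", key, ": "), lines, value = TRUE)
        if (!length(ln)) stop("missing key ", key, " in ", path)
        sub(paste0("^", key, ": "), "", ln[1])
    }
    edgeLines <- grep("^edge: ", lines, value = TRUE)
    edges <- if (length(edgeLines)) {
        parts <- strsplit(sub("^edge: ", "", edgeLines), " ")
        data.frame(task = vapply(parts, `[`, character(1), 1L),
                   roi_i = as.integer(vapply(parts, `[`, character(1), 2L)),
                   roi_j = as.integer(vapply(parts, `[`, character(1), 3L)),
                   effect = as.numeric(vapply(parts, `[`, character(1), 4L)))
    } else {
        data.frame(task = character(0), roi_i = integer(0),
                   roi_j = integer(0), effect = numeric(0))
    }
    plantedTruth(edges, baseCorr = as.numeric(getv("baseCorr")),
                 noiseSd = as.numeric(getv("noiseSd")),
                 seed = as.integer(getv("seed")))
}

#' Archive an FC dataset with checksum verification
#'
#' `writeFCArchive` serializes the dataset and writes an md5 checksum
#' sidecar (`<path>.md5`); `readFCArchive` verifies the checksum before
#' deserializing, so truncation or corruption is detected.
#'
#' @param dataset an [FCDataset-class].
#' @param path archive path (`.rds`).
#' @return `path` invisibly; `readFCArchive` returns the dataset.
#' @export
writeFCArchive <- function(dataset, path) {
    stopifnot(is(dataset, "FCDataset"))
    saveRDS(dataset, path)
    writeLines(unname(tools::md5sum(path)), paste0(path, ".md5"))
    invisible(path)
}

#' @rdname writeFCArchive
#' @export
readFCArchive <- function(path) {
    side <- paste0(path, ".md5")
    if (file.exists(side)) {
        expected <- readLines(side, n = 1L)
        actual <- unname(tools::md5sum(path))
        if (!identical(expected, actual))
            stop("checksum mismatch for ", path, "; archive corrupt?")
    }
    obj <- readRDS(path)
    if (!is(obj, "FCDataset")) stop("archive does not contain an FCDataset")
    validObject(obj)
    obj
}

#' Write an ideology score matrix as tab-delimited text
#'
#' @param scores an [IdeologyScoreMatrix-class].
#' @param path output file. Fold assignments are stored in a `fold`
#'   column when present.
#' @return `path` invisibly; `readScoreMatrix` the parsed object
#'   (without fold models).
#' @export
writeScoreMatrix <- function(scores, path) {
    stopifnot(is(scores, "IdeologyScoreMatrix"))
    S <- scoreValues(scores)
    d <- data.frame(subject_id = rownames(S), S, check.names = FALSE)
    if (length(foldAssignment(scores)))
        d$fold <- foldAssignment(scores)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeScoreMatrix
#' @export
readScoreMatrix <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
    fold <- if ("fold" %in% names(d)) as.integer(d$fold) else integer(0)
    taskCols <- setdiff(names(d), c("subject_id", "fold"))
    S <- as.matrix(d[, taskCols, drop = FALSE])
    rownames(S) <- d$subject_id
    new("IdeologyScoreMatrix", scores = S, foldAssignment = fold,
        models = list(), seed = NA_integer_)
}

#' Configure an end-to-end pipeline run
#'
#' Bundles every stage parameter: simulation sizes, planted truth, fold
#' count, hyperparameter search space, Monte Carlo settings and the
#' design-decision switches, all seeded from a single integer.
#'
#' @param nSubjects,nRois,nTimepoints simulation dimensions.
#' @param tasks task identifiers.
#' @param ideologyCounts length-6 ideology histogram summing to
#'   `nSubjects`.
#' @param covariateTargets named covariate-ideology correlation targets.
#' @param truth a [PlantedTruth-class] (default: no planted signal).
#' @param missingRoi ROI rendered all-missing in the simulation.
#' @param k cross-validation folds.
#' @param space a [searchSpace()].
#' @param mcSamples Monte Carlo comparison samples.
#' @param testFractionRange test-fraction range for [monteCarloCV()].
#' @param atlasPath atlas table path (`NULL` = packaged default; must
#'   exist and cover the retained ROIs when saliency is requested).
#' @param saliencyTasks tasks to run saliency for (default: all).
#' @param stratify stratify CV folds by ideology.
#' @param seed master seed.
#' @return Classed configuration list.
#' @export
pipelineConfig <- function(nSubjects = 60L, nRois = 40L, nTimepoints = 120L,
                           tasks = paste0("task", 1:3),
                           ideologyCounts = NULL,
                           covariateTargets = referenceCovariateTargets(),
                           truth = plantedTruth(),
                           missingRoi = NULL, k = 5L,
                           space = searchSpace(
                               nE2nFilters = 4L, nN2gUnits = 2L,
                               learningRate = 0.02, nEpochs = 15L,
                               batchSize = 16L, nDraws = 1L),
                           mcSamples = 100L,
                           testFractionRange = c(0.05, 0.50),
                           atlasPath = NULL, saliencyTasks = tasks,
                           stratify = FALSE, seed = 1L) {
    if (is.null(ideologyCounts)) {
        ideologyCounts <- round(referenceIdeologyCounts() * nSubjects / 174)
        ideologyCounts[2] <- ideologyCounts[2] +
            (nSubjects - sum(ideologyCounts))
    }
    if (!is.null(atlasPath) && !file.exists(atlasPath))
        stop("atlas path does not exist: ", atlasPath)
    cfg <- list(nSubjects = .checkScalarCount(nSubjects, "nSubjects", 10L),
                nRois = .checkScalarCount(nRois, "nRois", 4L),
                nTimepoints = .checkScalarCount(nTimepoints, "nTimepoints",
                                                30L),
                tasks = tasks, ideologyCounts = as.integer(ideologyCounts),
                covariateTargets = covariateTargets, truth = truth,
                missingRoi = missingRoi, k = .checkScalarCount(k, "k", 2L),
                space = space,
                mcSamples = .checkScalarCount(mcSamples, "mcSamples"),
                testFractionRange = testFractionRange,
                atlasPath = atlasPath, saliencyTasks = saliencyTasks,
                stratify = isTRUE(stratify), seed = as.integer(seed))
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Run the full pipeline: simulate, FC, train, analyze, compare, explain
#'
#' Executes every stage in order — cohort and BOLD simulation, FC
#' construction, out-of-fold network scoring, score correlations and
#' PCA, Monte Carlo model comparison against the Parent Conservatism
#' benchmark, LASSO variable importance, and gradient saliency — writing
#' each artifact as tab-delimited text (plus an FC archive) together
#' with a JSON manifest recording seeds and settings. A failing stage
#' halts with an error naming the stage.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created).
#' @return Invisibly, a list with the in-memory stage results; artifacts
#'   are under `outDir`.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("run")) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    stage <- function(name, expr) {
        message("[", name, "] ...")
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    atlas <- stage("config", {
        if (length(config$saliencyTasks)) readAtlas(config$atlasPath)
        else NULL
    })
    cohort <- stage("simulate", {
        co <- generateCohort(config$nSubjects, config$ideologyCounts,
                             config$covariateTargets,
                             seed = .deriveSeed(config$seed, 41L))
        writeCohort(co, file.path(outDir, "cohort.tsv"))
        writePlantedTruth(config$truth, file.path(outDir, "truth.txt"))
        co
    })
    series <- stage("simulate", generateBoldTimeSeries(
        cohort, config$truth, nRois = config$nRois,
        nTimepoints = config$nTimepoints, tasks = config$tasks,
        missingRoi = config$missingRoi))
    dataset <- stage("fc", {
        ds <- assembleDataset(series)
        writeFCArchive(ds, file.path(outDir, "fc_dataset.rds"))
        utils::write.table(ds@manifest, file.path(outDir, "fc_manifest.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        ds
    })
    scores <- stage("train", {
        sc <- crossValidatedScores(dataset, cohort, k = config$k,
                                   space = config$space,
                                   seed = .deriveSeed(config$seed, 43L),
                                   stratify = config$stratify)
        writeScoreMatrix(sc, file.path(outDir, "scores.tsv"))
        sc
    })
    analysis <- stage("score-analysis", {
        reports <- do.call(rbind, lapply(c("overall", "moderate", "extreme"),
            function(sg) tryCatch(correlateScores(scores, cohort, sg),
                                  error = function(e) {
                                      message("  skipping subgroup ", sg,
                                              ": ", conditionMessage(e))
                                      NULL
                                  })))
        utils::write.table(reports, file.path(outDir, "correlations.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        pca <- pcaScores(scores)
        utils::write.table(
            data.frame(component = seq_along(pca@varianceFraction),
                       variance_pct = pca@varianceFraction),
            file.path(outDir, "pca_variance.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(
            data.frame(task = rownames(pca@contributions),
                       round(pca@contributions, 3)),
            file.path(outDir, "pca_contributions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
        list(correlations = reports, pca = pca)
    })
    comparison <- stage("compare", {
        features <- assembleFeatures(scores, cohort)
        labels <- dichotomize(cohort)[match(rownames(features),
                                            subjectIds(cohort))]
        models <- list(parentConservatismSpec(), surveyModelSpec(),
                       fcModelSpec(config$tasks),
                       combinedModelSpec(config$tasks))
        res <- monteCarloCV(models, features, labels,
                            nSamples = config$mcSamples,
                            testFractionRange = config$testFractionRange,
                            seed = .deriveSeed(config$seed, 47L))
        tab <- compareToBenchmark(res)
        utils::write.table(tab, file.path(outDir, "model_comparison.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        list(result = res, table = tab, features = features,
             labels = labels)
    })
    importance <- stage("importance", {
        imp <- variableImportance(comparison$features, comparison$labels,
                                  seed = .deriveSeed(config$seed, 53L))
        utils::write.table(imp, file.path(outDir, "importance.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        imp
    })
    saliency <- stage("saliency", {
        if (!length(config$saliencyTasks)) return(NULL)
        res <- lapply(config$saliencyTasks, function(tk) {
            sal <- computeSaliency(scores, dataset, tk, atlas)
            utils::write.table(
                sal@regionTable,
                file.path(outDir, paste0("saliency_regions_", tk, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
            sal
        })
        names(res) <- config$saliencyTasks
        edges <- do.call(rbind, lapply(res, function(s) data.frame(
            task = s@taskId,
            liberal_i = s@topLiberal[1], liberal_j = s@topLiberal[2],
            conservative_i = s@topConservative[1],
            conservative_j = s@topConservative[2])))
        utils::write.table(edges, file.path(outDir, "saliency_top_edges.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        res
    })
    manifest <- list(
        package = "ideoconn",
        version = as.character(utils::packageVersion("ideoconn")),
        seed = config$seed,
        nSubjects = config$nSubjects, nRois = config$nRois,
        tasks = config$tasks, k = config$k,
        mcSamples = config$mcSamples,
        created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(list(cohort = cohort, dataset = dataset, scores = scores,
                   analysis = analysis, comparison = comparison,
                   importance = importance, saliency = saliency,
                   outDir = outDir))
}
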