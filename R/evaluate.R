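#' @include ContactGrid-methods.R features.R model.R baselines.R
NULL

#' Mean squared error between two contact maps
#'
#' The mean of squared differences over the upper-triangle entries;
#' the diagonal is excluded by default because training never samples it.
#'
#' @param predicted,observed [ContactMap]s (or matrices) with identical
#'   shape and retained bins.
#' @param includeDiagonal Include the diagonal in the mean.
#' @return A single number.
#' @export
mapMSE <- function(predicted, observed, includeDiagonal = FALSE) {
    p <- if (is(predicted, "ContactMap")) predicted@values else predicted
    o <- if (is(observed, "ContactMap")) observed@values else observed
    if (!identical(dim(p), dim(o))) {
        stop("maps have different shapes", call. = FALSE)
    }
    if (is(predicted, "ContactMap") && is(observed, "ContactMap") &&
            !identical(predicted@retainedBins, observed@retainedBins)) {
        stop("maps have different retained bins", call. = FALSE)
    }
    sel <- upper.tri(p, diag = includeDiagonal)
    mean((p[sel] - o[sel])^2)
}

#' Pearson correlation per genomic distance
#'
#' For each bin separation `d`, the Pearson correlation between the
#' entries of the two maps along diagonal `d`. Distances with fewer than
#' two pairs, or with zero variance in either map, are `NA`.
#'
#' @param predicted,observed [ContactMap]s (or matrices) of equal shape.
#' @return Numeric vector of length `nBins` (`d = 0 .. nBins - 1`).
#' @export
perDistanceCorrelation <- function(predicted, observed) {
    p <- if (is(predicted, "ContactMap")) predicted@values else predicted
    o <- if (is(observed, "ContactMap")) observed@values else observed
    if (!identical(dim(p), dim(o))) {
        stop("maps have different shapes", call. = FALSE)
    }
    n <- nrow(p)
    d <- col(p) - row(p)
    vapply(0:(n - 1L), function(k) {
        x <- p[d == k]
        y <- o[d == k]
        if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0) {
            return(NA_real_)
        }
        stats::cor(x, y)
    }, numeric(1))
}

#' Regress test MSE on shared-training-experiment counts
#'
#' For each test map, counts how many training experiments share its
#' assay, its biosample, or either, and fits an ordinary least squares
#' line of the test MSE on each of the three counts. A predictor with
#' zero variance yields an `NA` fit.
#'
#' @param mseTable Data frame with columns `biosample`, `assay`, `mse`
#'   (one row per test map).
#' @param split Split assignment from [splitExperiments()].
#' @return Data frame with one row per predictor (`sharedAssay`,
#'   `sharedBiosample`, `sharedEither`): `slope`, `intercept`,
#'   `rSquared`, `n`.
#' @export
mseVsSharedTraining <- function(mseTable, split) {
    if (nrow(mseTable) < 3L) {
        stop("at least three test maps are required", call. = FALSE)
    }
    train <- split[split$split == "train", , drop = FALSE]
    counts <- data.frame(
        sharedAssay = vapply(seq_len(nrow(mseTable)), function(r) {
            sum(train$assay == mseTable$assay[r])
        }, numeric(1)),
        sharedBiosample = vapply(seq_len(nrow(mseTable)), function(r) {
            sum(train$biosample == mseTable$biosample[r])
        }, numeric(1))
    )
    counts$sharedEither <- counts$sharedAssay + counts$sharedBiosample
    fits <- lapply(names(counts), function(nm) {
        x <- counts[[nm]]
        if (stats::sd(x) == 0) {
            return(data.frame(predictor = nm, slope = NA_real_,
                              intercept = NA_real_, rSquared = NA_real_,
                              n = nrow(mseTable)))
        }
        fit <- stats::lm(mseTable$mse ~ x)
        data.frame(predictor = nm, slope = unname(stats::coef(fit)[2L]),
                   intercept = unname(stats::coef(fit)[1L]),
                   rSquared = summary(fit)$r.squared, n = nrow(mseTable))
    })
    do.call(rbind, fits)
}

#' Random search over a hyperparameter grid
#'
#' Samples `nSamples` configurations uniformly from the Cartesian product
#' of the per-dimension value lists (without replacement when the grid is
#' large enough, with replacement otherwise), trains each with
#' [trainContactModel()], and records the best validation MSE and epoch.
#'
#' @param searchGrid Named list of candidate value vectors, names matching
#'   [defaultHyperparams()] fields (e.g. `list(learningRate = c(1e-4,
#'   5e-4), nNodes = c(64, 256))`).
#' @param nSamples Number of configurations to try (500 at study scale).
#' @param grid,split Passed to [trainContactModel()].
#' @param seed Seed for both the configuration sample and each training
#'   run.
#' @param baseHyperparams Defaults for dimensions not searched.
#'
#' @return A list with `table` (one row per configuration, columns for
#'   each searched dimension plus `bestValidationMSE`, `bestEpoch`),
#'   `best` (the argmin row), `nSampled`, and `seed`.
#' @export
hyperparameterSearch <- function(searchGrid, nSamples, grid, split,
                                 seed = 1L,
                                 baseHyperparams = defaultHyperparams()) {
    if (!length(searchGrid) || any(!lengths(searchGrid))) {
        stop("every search dimension must be non-empty", call. = FALSE)
    }
    unknown <- setdiff(names(searchGrid), names(baseHyperparams))
    if (length(unknown)) {
        stop("unknown hyperparameters in search grid: ",
             paste(unknown, collapse = ", "), call. = FALSE)
    }
    sizes <- lengths(searchGrid)
    total <- prod(sizes)
    picks <- withSeed(seed, {
        if (total >= nSamples) {
            sample(total, nSamples)
        } else {
            sample(total, nSamples, replace = TRUE)
        }
    })
    decode <- function(k) {
        k <- k - 1L
        idx <- integer(length(sizes))
        for (d in seq_along(sizes)) {
            idx[d] <- k %% sizes[d] + 1L
            k <- k %/% sizes[d]
        }
        stats::setNames(lapply(seq_along(sizes), function(d) {
            searchGrid[[d]][idx[d]]
        }), names(searchGrid))
    }
    rows <- lapply(seq_along(picks), function(r) {
        config <- decode(picks[r])
        hp <- baseHyperparams
        hp[names(config)] <- config
        model <- trainContactModel(grid, split, hyperparams = hp,
                                   seed = seed + r)
        hist <- trainingHistory(model)
        best <- hist[hist$epoch == bestEpoch(model), ]
        cbind(as.data.frame(config),
              data.frame(bestValidationMSE = best$validationMSE,
                         bestEpoch = bestEpoch(model)))
    })
    table <- do.call(rbind, rows)
    list(table = table,
         best = table[which.min(table$bestValidationMSE), , drop = FALSE],
         nSampled = length(picks), seed = as.integer(seed))
}

#' Impute every missing cell of a grid
#'
#' Produces a complete grid by filling each unobserved (biosample, assay)
#' cell with either a model prediction or a mean baseline.
#'
#' @param grid A (normalized) [ContactGrid].
#' @param method `"model"`, `"cross"`, `"row"`, or `"column"`.
#' @param model A trained [ContactModel] (required for
#'   `method = "model"`).
#' @param split Optional split restricting the baseline pools.
#' @return A complete [ContactGrid].
#' @export
completeGrid <- function(grid, method = c("model", "cross", "row", "column"),
                         model = NULL, split = NULL) {
    method <- match.arg(method)
    if (method == "model" && is.null(model)) {
        stop("method = 'model' requires a trained model", call. = FALSE)
    }
    template <- grid@maps[[1L]]
    for (b in biosamples(grid)) {
        for (a in assays(grid)) {
            if (isObserved(grid, b, a)) next
            pred <- switch(method,
                model = predictContactMap(model, b, a, template = template),
                cross = crossMeanImpute(grid, b, a, split = split),
                row = rowMeanImpute(grid, b, a, split = split),
                column = columnMeanImpute(grid, b, a, split = split))
            grid <- setMapAt(grid, b, a, pred)
        }
    }
    grid
}

#' Mean feature correlation between entities
#'
#' For two entities on the chosen axis (two biosamples, say), every entity
#' on the other axis (assay `a`) for which both maps `(c1, a)` and
#' `(c2, a)` are present yields a Pearson correlation between the two
#' maps' feature profiles; the matrix entry is the mean of those
#' correlations. With a partial grid, unavailable experiments are
#' skipped and entries with no shared experiment are `NA`; on a complete
#' (imputed) grid the matrix is complete. Feature pairs where either
#' profile has zero variance contribute `NA` and are excluded from the
#' mean.
#'
#' @param grid A [ContactGrid], complete or partial.
#' @param axis `"biosample"` or `"assay"` (the entities being compared).
#' @param feature `"decay"`, `"eigenvector"`, or `"insulation"`.
#' @param window Insulation window, if used.
#'
#' @return A list of class `"entityCorrelation"`: `entities`, `r`
#'   (correlation matrix), `nShared` (shared-experiment counts),
#'   `feature`, `axis`, `imputed` (TRUE when the grid was complete).
#' @export
entityCorrelation <- function(grid, axis = c("biosample", "assay"),
                              feature = c("decay", "eigenvector",
                                          "insulation"),
                              window = 30L) {
    axis <- match.arg(axis)
    feature <- match.arg(feature)
    entities <- if (axis == "biosample") biosamples(grid) else assays(grid)
    others <- if (axis == "biosample") assays(grid) else biosamples(grid)
    at <- function(ent, oth) {
        if (axis == "biosample") c(ent, oth) else c(oth, ent)
    }
    profiles <- new.env(parent = emptyenv())
    getProfile <- function(ent, oth) {
        key <- gridKey(at(ent, oth)[1L], at(ent, oth)[2L])
        if (is.null(profiles[[key]])) {
            ba <- at(ent, oth)
            profiles[[key]] <- profileValues(
                computeFeature(mapAt(grid, ba[1L], ba[2L]), feature,
                               window = window))
        }
        profiles[[key]]
    }
    nE <- length(entities)
    r <- matrix(NA_real_, nE, nE, dimnames = list(entities, entities))
    nShared <- matrix(0L, nE, nE, dimnames = list(entities, entities))
    for (p in seq_len(nE)) {
        for (q in seq_len(p)) {
            shared <- Filter(function(oth) {
                ba1 <- at(entities[p], oth)
                ba2 <- at(entities[q], oth)
                isObserved(grid, ba1[1L], ba1[2L]) &&
                    isObserved(grid, ba2[1L], ba2[2L])
            }, others)
            nShared[p, q] <- nShared[q, p] <- length(shared)
            if (!length(shared)) next
            cors <- vapply(shared, function(oth) {
                x <- getProfile(entities[p], oth)
                y <- getProfile(entities[q], oth)
                if (stats::sd(x) == 0 || stats::sd(y) == 0) {
                    return(NA_real_)
                }
                stats::cor(x, y)
            }, numeric(1))
            cors <- cors[!is.na(cors)]
            if (length(cors)) {
                r[p, q] <- r[q, p] <- mean(cors)
            }
        }
    }
    total <- length(entities) * length(others)
    structure(list(entities = entities, r = r, nShared = nShared,
                   feature = feature, axis = axis,
                   imputed = nObserved(grid) == total),
              class = "entityCorrelation")
}

#' @export
print.entityCorrelation <- function(x, ...) {
    cat("entityCorrelation over ", length(x$entities), " ", x$axis,
        "s (feature: ", x$feature, ", ",
        if (x$imputed) "complete grid" else "partial grid", ")\n", sep = "")
    print(round(x$r, 3))
    invisible(x)
}

#' Hierarchical clustering of entities from a correlation matrix
#'
#' Agglomerative clustering on the distance `1 - r` with average linkage
#' (configurable). Requires a complete correlation matrix, i.e. one
#' computed on an imputed grid; entities are ordered lexicographically
#' first so that ties merge deterministically.
#'
#' @param corr An `"entityCorrelation"` result with no missing entries.
#' @param method Linkage passed to [stats::hclust()].
#' @return An object of class `hclust` (merge list with heights).
#' @export
clusterEntities <- function(corr, method = "average") {
    if (anyNA(corr$r)) {
        stop("correlation matrix has missing entries; impute the grid ",
             "first (see completeGrid)", call. = FALSE)
    }
    ord <- order(corr$entities)
    r <- corr$r[ord, ord]
    stats::hclust(stats::as.dist(1 - r), method = method)
}

#' Per-map imputation error table
#'
#' Computes, for every held-out map of the requested split, the MSE of the
#' model prediction and of the three mean baselines against the observed
#' (normalized) map.
#'
#' @param grid Normalized [ContactGrid].
#' @param split Split assignment.
#' @param model Trained [ContactModel].
#' @param evalSplit Which split to evaluate (`"validation"` or
#'   `"test"`).
#' @param includeDiagonal Passed to [mapMSE()].
#' @return Data frame with one row per (map, method): columns
#'   `biosample`, `assay`, `method`, `mse`.
#' @export
evaluateImputation <- function(grid, split, model,
                               evalSplit = c("validation", "test"),
                               includeDiagonal = FALSE) {
    evalSplit <- match.arg(evalSplit)
    rows <- split[split$split == evalSplit, , drop = FALSE]
    out <- list()
    for (r in seq_len(nrow(rows))) {
        b <- rows$biosample[r]
        a <- rows$assay[r]
        if (!isObserved(grid, b, a)) next
        obs <- mapAt(grid, b, a)
        preds <- list(
            model = if (!is.null(model))
                predictContactMap(model, b, a, template = obs) else NULL,
            row = tryCatch(rowMeanImpute(grid, b, a, split = split),
                           error = function(e) NULL),
            column = tryCatch(columnMeanImpute(grid, b, a, split = split),
                              error = function(e) NULL),
            cross = tryCatch(crossMeanImpute(grid, b, a, split = split),
                             error = function(e) NULL)
        )
        for (m in names(preds)) {
            if (is.null(preds[[m]])) next
            out[[length(out) + 1L]] <- data.frame(
                biosample = b, assay = a, method = m,
                mse = mapMSE(preds[[m]], obs,
                             includeDiagonal = includeDiagonal))
        }
    }
    do.call(rbind, out)
}

#' Remove a fraction of the training experiments from a split
#'
#' Ablation helper: drops a random subset of the training-split rows
#' (validation and test assignments are untouched), so a model can be
#' retrained on fewer experiments to measure how performance depends on
#' training-set size.
#'
#' @param split Split assignment from [splitExperiments()].
#' @param fraction Fraction of training experiments to remove.
#' @param seed Seed for the random subset.
#' @return The reduced split data frame.
#' @export
dropTrainExperiments <- function(split, fraction = 0.5, seed = 1L) {
    trn <- which(split$split == "train")
    nDrop <- floor(length(trn) * fraction)
    if (nDrop == 0L) {
        return(split)
    }
    drop <- withSeed(seed, sample(trn, nDrop))
    out <- split[-drop, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "seed") <- attr(split, "seed")
    out
}
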