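#' @include AllClasses.R AllGenerics.R ContactGrid-methods.R preprocess.R
#' @useDynLib contactImpute, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Default model hyperparameters
#'
#' The default configuration: 16 biosample factors, 128 assay factors, 128
#' position factors, 128 distance factors, 4 hidden layers of 256
#' rectified-linear units with dropout 0.4, Adam with initial learning rate
#' 1e-4, batches of 10,000 off-diagonal matrix entries, 526 batches per
#' epoch, and at most 50 epochs with per-epoch validation for model
#' selection. Any subset can be overridden.
#'
#' @param ... Named overrides, e.g. `defaultHyperparams(epochs = 10)`.
#' @return Named list of hyperparameters.
#' @export
defaultHyperparams <- function(...) {
    hp <- list(
        learningRate = 1e-4,
        dropout = 0.4,
        nBiosampleFactors = 16L,
        nAssayFactors = 128L,
        nPositionFactors = 128L,
        nDistanceFactors = 128L,
        nLayers = 4L,
        nNodes = 256L,
        epochs = 50L,
        batchSize = 10000L,
        batchesPerEpoch = 526L,
        patience = 0L,          # 0 disables early stopping
        valIncludeDiagonal = FALSE
    )
    overrides <- list(...)
    unknown <- setdiff(names(overrides), names(hp))
    if (length(unknown)) {
        stop("unknown hyperparameters: ", paste(unknown, collapse = ", "),
             call. = FALSE)
    }
    hp[names(overrides)] <- overrides
    validateHyperparams(hp)
    hp
}

validateHyperparams <- function(hp) {
    pos <- c("learningRate", "nBiosampleFactors", "nAssayFactors",
             "nPositionFactors", "nDistanceFactors", "nLayers", "nNodes",
             "epochs", "batchSize", "batchesPerEpoch")
    for (f in pos) {
        if (!is.numeric(hp[[f]]) || length(hp[[f]]) != 1L || hp[[f]] <= 0) {
            stop("hyperparameter ", f, " must be a positive scalar",
                 call. = FALSE)
        }
    }
    if (hp$dropout < 0 || hp$dropout >= 1) {
        stop("dropout must lie in [0, 1)", call. = FALSE)
    }
    invisible(hp)
}

# internal: embedding tables + layer list in the form the C++ core expects
modelParams <- function(model) {
    list(
        embeddings = list(
            biosample = model@biosampleEmbedding,
            assay = model@assayEmbedding,
            position = model@positionEmbedding,
            distance = model@distanceEmbedding
        ),
        layers = model@layers
    )
}

#' Initialize a contact model
#'
#' Creates embedding tables for biosamples, assays, genomic bins, and
#' bin-pair distances (one row per separation `0 .. nBins - 1`), and the
#' dense layers of the multilayer perceptron. Embedding entries are drawn
#' from N(0, 0.1); hidden-layer weights use scaled (He) normal
#' initialization and zero biases. Deterministic given `seed`.
#'
#' @param biosamples,assays Labels the model will cover.
#' @param nBins Number of (retained) bins.
#' @param hyperparams See [defaultHyperparams()].
#' @param seed Integer seed.
#' @param variant `"mlp"` for the standard model, `"conv"` to add the
#'   convolutional position-window encoder (see [convForwardPass()]).
#'
#' @return An untrained [ContactModel].
#' @export
initContactModel <- function(biosamples, assays, nBins,
                             hyperparams = defaultHyperparams(), seed = 1L,
                             variant = c("mlp", "conv")) {
    variant <- match.arg(variant)
    validateHyperparams(hyperparams)
    checkLabel(biosamples, "biosample")
    checkLabel(assays, "assay")
    nBins <- as.integer(nBins)
    if (nBins < 2L) {
        stop("nBins must be at least 2", call. = FALSE)
    }
    hp <- hyperparams
    inDim <- hp$nBiosampleFactors + hp$nAssayFactors +
        2L * hp$nPositionFactors + hp$nDistanceFactors
    withSeed(seed, {
        emb <- function(n, k) matrix(stats::rnorm(n * k, sd = 0.1), n, k)
        dense <- function(fanIn, fanOut) {
            list(W = matrix(stats::rnorm(fanIn * fanOut,
                                         sd = sqrt(2 / fanIn)),
                            fanIn, fanOut),
                 b = numeric(fanOut))
        }
        Eb <- emb(length(biosamples), hp$nBiosampleFactors)
        Ea <- emb(length(assays), hp$nAssayFactors)
        Ep <- emb(nBins, hp$nPositionFactors)
        Ed <- emb(nBins, hp$nDistanceFactors)
        layers <- vector("list", hp$nLayers + 1L)
        layers[[1L]] <- dense(inDim, hp$nNodes)
        for (l in seq_len(hp$nLayers - 1L)) {
            layers[[l + 1L]] <- dense(hp$nNodes, hp$nNodes)
        }
        layers[[hp$nLayers + 1L]] <- dense(hp$nNodes, 1L)
        conv <- list()
        if (variant == "conv") {
            conv <- list(
                W1 = matrix(stats::rnorm(3L * 21L, sd = sqrt(2 / 21)),
                            3L, 21L),
                b1 = numeric(3L),
                W2 = stats::rnorm(3L, sd = sqrt(2 / 3)),
                b2 = 0
            )
        }
        new("ContactModel", biosamples = as.character(biosamples),
            assays = as.character(assays), nBins = nBins,
            hyperparams = hp, biosampleEmbedding = Eb, assayEmbedding = Ea,
            positionEmbedding = Ep, distanceEmbedding = Ed,
            layers = layers, conv = conv, variant = variant,
            history = data.frame(epoch = integer(0), trainLoss = numeric(0),
                                 validationMSE = numeric(0)),
            bestEpoch = 0L, seed = as.integer(seed))
    })
}

setMethod("show", "ContactModel", function(object) {
    hp <- object@hyperparams
    cat("ContactModel (", object@variant, "): ",
        length(object@biosamples), " biosamples x ",
        length(object@assays), " assays, ", object@nBins, " bins\n",
        sep = "")
    cat("  factors: ", hp$nBiosampleFactors, "/", hp$nAssayFactors, "/",
        hp$nPositionFactors, "/", hp$nDistanceFactors,
        " (biosample/assay/position/distance)\n", sep = "")
    cat("  MLP: ", hp$nLayers, " x ", hp$nNodes, " units, dropout ",
        hp$dropout, ", lr ", hp$learningRate, "\n", sep = "")
    if (object@bestEpoch > 0L) {
        v <- object@history$validationMSE[
            object@history$epoch == object@bestEpoch]
        cat("  trained: best epoch ", object@bestEpoch,
            ", validation MSE ", format(v), "\n", sep = "")
    } else {
        cat("  untrained\n")
    }
})

#' @rdname trainingHistory
#' @param x A [ContactModel].
#' @export
setMethod("trainingHistory", "ContactModel", function(x) x@history)

#' Training history and selected epoch
#'
#' `trainingHistory` returns the per-epoch train loss and validation MSE
#' (epoch 0 is the random initialization); `bestEpoch` the epoch whose
#' parameter snapshot the model holds.
#'
#' @name trainingHistory
NULL

#' @rdname trainingHistory
#' @export
setMethod("bestEpoch", "ContactModel", function(x) x@bestEpoch)

# internal: map labels/indices to 0-based index vectors
resolveIndex <- function(values, labels, what) {
    if (is.character(values)) {
        idx <- match(values, labels)
        if (anyNA(idx)) {
            stop("unknown ", what, " label: ",
                 values[which(is.na(idx))[1L]], call. = FALSE)
        }
        idx - 1L
    } else {
        idx <- as.integer(values)
        if (any(idx < 1L) || any(idx > length(labels))) {
            stop(what, " index out of range", call. = FALSE)
        }
        idx - 1L
    }
}

#' Evaluation-mode forward pass
#'
#' Predicts the normalized contact value for each (biosample, assay,
#' position i, position j) query. Queries are canonicalized to
#' `(min(i, j), max(i, j))` before embedding lookup, so the output is
#' exactly symmetric in the two positions, and dropout is inactive, so
#' repeated calls are deterministic.
#'
#' @param model A [ContactModel].
#' @param biosample,assay Labels (or 1-based indices) of the target
#'   experiment; recycled to the length of `i`.
#' @param i,j 1-based bin indices of the two genomic positions.
#'
#' @return Numeric vector of predictions, one per query.
#' @export
forwardPass <- function(model, biosample, assay, i, j) {
    stopifnot(is(model, "ContactModel"))
    n <- max(length(biosample), length(assay), length(i), length(j))
    b <- rep_len(resolveIndex(biosample, model@biosamples, "biosample"), n)
    a <- rep_len(resolveIndex(assay, model@assays, "assay"), n)
    i <- rep_len(as.integer(i), n)
    j <- rep_len(as.integer(j), n)
    if (any(i < 1L) || any(i > model@nBins) || any(j < 1L) ||
            any(j > model@nBins)) {
        stop("bin index out of range [1, ", model@nBins, "]", call. = FALSE)
    }
    if (model@variant == "conv") {
        return(convForwardPass(model, b + 1L, a + 1L, i, j,
                               .resolved = TRUE))
    }
    p <- modelParams(model)
    queries <- cbind(b, a, i - 1L, j - 1L)
    storage.mode(queries) <- "integer"
    cpp_forward(p$embeddings, p$layers, queries)
}

#' Sample a training batch of off-diagonal matrix entries
#'
#' Draws `batchSize` examples uniformly with replacement over all
#' (training experiment, unordered off-diagonal bin pair) combinations,
#' using the session RNG. Targets are read from the supplied (normalized)
#' maps. Pairs are canonicalized to `i < j`; diagonal entries are never
#' sampled.
#'
#' @param trainMaps Named list of [ContactMap]s (the training
#'   experiments).
#' @param batchSize Number of examples.
#'
#' @return Data frame with columns `experiment` (index into `trainMaps`),
#'   `i`, `j` (1-based, `i < j`), and `target`.
#' @export
sampleTrainingBatch <- function(trainMaps, batchSize = 10000L) {
    if (!length(trainMaps)) {
        stop("at least one training map is required", call. = FALSE)
    }
    n <- nBins(trainMaps[[1L]])
    nPairs <- n * (n - 1L) / 2
    expIdx <- sample.int(length(trainMaps), batchSize, replace = TRUE)
    k <- sample.int(nPairs, batchSize, replace = TRUE)
    # decode linear index over pairs enumerated row by row (i < j)
    pairRow <- rep.int(seq_len(n - 1L), (n - 1L):1L)
    pairCol <- sequence((n - 1L):1L) + pairRow
    i <- pairRow[k]
    j <- pairCol[k]
    target <- vapply(seq_len(batchSize), function(r) {
        contactValues(trainMaps[[expIdx[r]]])[i[r], j[r]]
    }, numeric(1))
    data.frame(experiment = expIdx, i = i, j = j, target = target)
}

#' Train a contact model
#'
#' Fits the deep factorization model on the training-split maps of a
#' normalized grid by minimizing mean squared error over randomly sampled
#' off-diagonal matrix entries with Adam. After every epoch the full
#' validation MSE (all upper-triangle off-diagonal entries of every
#' validation map) is computed, and the returned model holds the parameter
#' snapshot of the epoch with the lowest validation MSE. Training is
#' deterministic given `seed`.
#'
#' @param grid A normalized [ContactGrid] (see [preprocessGrid()]).
#' @param split Split assignment from [splitExperiments()]; must contain
#'   at least one training and one validation experiment observed in
#'   `grid`.
#' @param hyperparams See [defaultHyperparams()]. `epochs`, `batchSize`,
#'   and `batchesPerEpoch` control the training budget; `patience > 0`
#'   stops training after that many epochs without validation
#'   improvement.
#' @param seed Integer seed for initialization, batch sampling, and
#'   dropout.
#'
#' @return A trained [ContactModel] with full training history.
#' @export
trainContactModel <- function(grid, split,
                              hyperparams = defaultHyperparams(),
                              seed = 1L) {
    stopifnot(is(grid, "ContactGrid"))
    validateHyperparams(hyperparams)
    obsKeys <- names(gridMaps(grid))
    trainK <- intersect(obsKeys, splitKeys(split, "train"))
    valK <- intersect(obsKeys, splitKeys(split, "validation"))
    if (!length(trainK)) {
        stop("no training experiments in split", call. = FALSE)
    }
    if (!length(valK)) {
        stop("no validation experiments in split; model selection ",
             "requires a validation set", call. = FALSE)
    }
    model <- initContactModel(biosamples(grid), assays(grid),
                              nBins(grid@maps[[1L]]), hyperparams, seed)
    p <- modelParams(model)
    keyIdx <- function(keys) {
        kk <- splitGridKey(keys)
        list(b = match(kk$biosample, model@biosamples) - 1L,
             a = match(kk$assay, model@assays) - 1L)
    }
    ti <- keyIdx(trainK)
    vi <- keyIdx(valK)
    rngSeed <- withSeed(seed, floor(stats::runif(1) * 2^31))
    fit <- cpp_train(
        p$embeddings, p$layers,
        lapply(grid@maps[trainK], contactValues), ti$b, ti$a,
        lapply(grid@maps[valK], contactValues), vi$b, vi$a,
        hyperparams$learningRate, hyperparams$dropout,
        as.integer(hyperparams$epochs), as.integer(hyperparams$batchSize),
        as.integer(hyperparams$batchesPerEpoch),
        as.integer(hyperparams$patience),
        isTRUE(hyperparams$valIncludeDiagonal), rngSeed)
    nEpochs <- length(fit$trainLoss)
    model@biosampleEmbedding <- fit$embeddings$biosample
    model@assayEmbedding <- fit$embeddings$assay
    model@positionEmbedding <- fit$embeddings$position
    model@distanceEmbedding <- fit$embeddings$distance
    model@layers <- fit$layers
    model@history <- data.frame(
        epoch = 0:nEpochs,
        trainLoss = c(NA_real_, fit$trainLoss),
        validationMSE = fit$validationMSE
    )
    model@bestEpoch <- as.integer(fit$bestEpoch)
    validObject(model)
    model
}

#' Predict a full contact map
#'
#' Runs the model in evaluation mode over all bin pairs `i <= j` for one
#' (biosample, assay) cell and reflects the predictions across the
#' diagonal, so the output is exactly symmetric. Diagonal entries are
#' model outputs at distance 0; training never samples the diagonal, so
#' they are an extrapolation (set `includeDiagonal = FALSE` to zero them
#' instead).
#'
#' @param model A trained [ContactModel].
#' @param biosample,assay Labels of the target cell; must be known to the
#'   model.
#' @param template Optional [ContactMap] supplying chrom/resolution/
#'   retained-bin bookkeeping for the output.
#' @param includeDiagonal Emit model outputs on the diagonal (default) or
#'   zeros.
#'
#' @return A [ContactMap] of predictions (negative values permitted:
#'   predictions are unconstrained regression outputs).
#' @export
predictContactMap <- function(model, biosample, assay, template = NULL,
                              includeDiagonal = TRUE) {
    stopifnot(is(model, "ContactModel"))
    n <- model@nBins
    ut <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
    pred <- forwardPass(model, biosample, assay, ut[, "row"], ut[, "col"])
    values <- matrix(0, n, n)
    values[ut] <- pred
    values[lower.tri(values)] <- t(values)[lower.tri(values)]
    if (!includeDiagonal) {
        diag(values) <- 0
    }
    if (is.null(template)) {
        ContactMap(values, allowNegative = TRUE)
    } else {
        setMapValues(template, values, allowNegative = TRUE)
    }
}

#' Forward pass of the convolutional position-encoder variant
#'
#' Instead of using a bin's embedding row directly, this variant stacks
#' the embedding rows of the 21 bins in a +/-10 window around each query
#' position (zero rows where the window leaves the chromosome) and reduces
#' the stack with two convolution stages: 1 input channel to 3 output
#' channels with a kernel spanning the 21-row window, then 3 channels to 1
#' with a 1x1 kernel. The reduced vectors replace the raw position rows in
#' the concatenated input; everything else matches [forwardPass()].
#' Queries are canonicalized before windowing, so swap symmetry is
#' preserved.
#'
#' @param model A [ContactModel] with `variant = "conv"`.
#' @param biosample,assay,i,j As in [forwardPass()].
#' @param .resolved Internal.
#'
#' @return Numeric vector of predictions.
#' @export
convForwardPass <- function(model, biosample, assay, i, j,
                            .resolved = FALSE) {
    stopifnot(is(model, "ContactModel"))
    if (model@variant != "conv" || !length(model@conv)) {
        stop("model was not initialized with variant = 'conv'",
             call. = FALSE)
    }
    n <- max(length(biosample), length(assay), length(i), length(j))
    if (.resolved) {
        b <- rep_len(as.integer(biosample) - 1L, n)
        a <- rep_len(as.integer(assay) - 1L, n)
    } else {
        b <- rep_len(resolveIndex(biosample, model@biosamples, "biosample"),
                     n)
        a <- rep_len(resolveIndex(assay, model@assays, "assay"), n)
    }
    i <- rep_len(as.integer(i), n)
    j <- rep_len(as.integer(j), n)
    lo <- pmin(i, j)
    hi <- pmax(i, j)
    conv <- model@conv
    # the two stages collapse to one effective kernel over the 21 window
    # rows plus a constant: sum_c W2[c] * (W1[c, ] . plane + b1[c]) + b2
    kernel <- as.numeric(conv$W2 %*% conv$W1)           # length 21
    const <- sum(conv$W2 * conv$b1) + conv$b2
    reduceAt <- function(pos) {
        # rows: embedding rows for pos-10 .. pos+10, zero outside [1, nBins]
        out <- matrix(const, length(pos), ncol(model@positionEmbedding))
        for (w in -10:10) {
            idx <- pos + w
            ok <- idx >= 1L & idx <= model@nBins
            if (any(ok)) {
                out[ok, ] <- out[ok, ] + kernel[w + 11L] *
                    model@positionEmbedding[idx[ok], , drop = FALSE]
            }
        }
        out
    }
    X <- cbind(
        model@biosampleEmbedding[b + 1L, , drop = FALSE],
        model@assayEmbedding[a + 1L, , drop = FALSE],
        reduceAt(lo),
        reduceAt(hi),
        model@distanceEmbedding[hi - lo + 1L, , drop = FALSE]
    )
    A <- X
    L <- length(model@layers)
    for (l in seq_len(L - 1L)) {
        Z <- A %*% model@layers[[l]]$W
        Z <- sweep(Z, 2L, model@layers[[l]]$b, `+`)
        A <- pmax(Z, 0)
    }
    out <- A %*% model@layers[[L]]$W + model@layers[[L]]$b
    as.numeric(out)
}

#' Save or load a model checkpoint
#'
#' A checkpoint is a single-file archive (schema-versioned RDS) holding
#' all embedding tables, dense-layer weights, hyperparameters, training
#' history, and the seed.
#'
#' @param model A [ContactModel].
#' @param path Checkpoint path.
#' @name checkpoint
NULL

#' @rdname checkpoint
#' @export
saveContactModel <- function(model, path) {
    stopifnot(is(model, "ContactModel"))
    payload <- list(schema = 1L,
                    slots = sapply(slotNames("ContactModel"),
                                   function(s) slot(model, s),
                                   simplify = FALSE))
    saveRDS(payload, path)
    invisible(path)
}

#' @rdname checkpoint
#' @export
readContactModel <- function(path) {
    payload <- readRDS(path)
    if (!identical(payload$schema, 1L)) {
        stop("unsupported checkpoint schema: ", payload$schema,
             call. = FALSE)
    }
    do.call(new, c(list("ContactModel"), payload$slots))
}
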