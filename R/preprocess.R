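#' @include ContactMap-methods.R ContactGrid-methods.R
NULL

#' Log-transform a contact map
#'
#' Replaces each entry x by `log(x + 1)` (natural log), taming the high
#' dynamic range of raw contact counts while keeping zeros at zero.
#'
#' @param map A [ContactMap] with non-negative entries.
#' @return The transformed [ContactMap].
#' @export
log1pMap <- function(map) {
    stopifnot(is(map, "ContactMap"))
    if (any(map@values < 0)) {
        stop("log1pMap requires non-negative entries", call. = FALSE)
    }
    setMapValues(map, log1p(map@values))
}

#' Marginal counts of a contact map
#'
#' The marginal of bin i is the sum of row i of the full symmetric matrix
#' (diagonal counted once).
#'
#' @param map A [ContactMap].
#' @return Numeric vector of length `nBins(map)`.
#' @export
binMarginals <- function(map) {
    stopifnot(is(map, "ContactMap"))
    rowSums(map@values)
}

#' Select bins to retain based on training-map marginals
#'
#' For each training map the marginal-count vector `m` is computed, along
#' with its median `M` and the median absolute deviation
#' `MAD = median(|m - M|)` (or the mean absolute deviation from the median
#' when `madKind = "mean"`). A bin is discarded when `|m[i] - M|` exceeds
#' `kMad * MAD` in *any* training map; the remaining bins form the mask.
#' When a map's MAD is zero (near-uniform marginals) that map discards no
#' bins. The mask is derived exclusively from training maps and is meant
#' to be applied unchanged to validation and test maps to avoid leakage.
#'
#' @param trainMaps List of [ContactMap]s (the training set), all with the
#'   same bin count.
#' @param kMad Deviation multiplier; default 10.
#' @param madKind `"median"` (median absolute deviation from the median)
#'   or `"mean"` (mean absolute deviation from the median).
#'
#' @return A [BinMask].
#' @export
selectRetainedBins <- function(trainMaps, kMad = 10,
                               madKind = c("median", "mean")) {
    madKind <- match.arg(madKind)
    if (!length(trainMaps)) {
        stop("at least one training map is required", call. = FALSE)
    }
    n <- nBins(trainMaps[[1L]])
    keep <- rep(TRUE, n)
    for (map in trainMaps) {
        if (nBins(map) != n) {
            stop("training maps disagree on bin count", call. = FALSE)
        }
        m <- binMarginals(map)
        dev <- abs(m - stats::median(m))
        mad <- switch(madKind, median = stats::median(dev), mean = mean(dev))
        if (mad > 0) {
            keep <- keep & (dev <= kMad * mad)
        }
    }
    if (sum(keep) < 2L) {
        stop("marginal filtering would discard all but ", sum(keep),
             " bins; lower kMad or inspect the maps", call. = FALSE)
    }
    new("BinMask", nBins = n, keep = keep)
}

#' @rdname BinMask-accessors
#' @param x A [BinMask].
#' @export
setMethod("keptBins", "BinMask", function(x) which(x@keep) - 1L)

setMethod("show", "BinMask", function(object) {
    cat("BinMask:", sum(object@keep), "of", object@nBins, "bins kept\n")
})

#' Apply a bin mask to a contact map
#'
#' Removes the rows and columns of discarded bins and updates the map's
#' retained-bin bookkeeping.
#'
#' @param map A [ContactMap] whose current bin count equals the mask
#'   length.
#' @param mask A [BinMask].
#' @return The masked [ContactMap].
#' @export
applyBinMask <- function(map, mask) {
    stopifnot(is(map, "ContactMap"), is(mask, "BinMask"))
    if (nBins(map) != mask@nBins) {
        stop("mask length (", mask@nBins, ") does not match map bins (",
             nBins(map), ")", call. = FALSE)
    }
    idx <- which(mask@keep)
    initialize(map, values = map@values[idx, idx, drop = FALSE],
               retainedBins = map@retainedBins[idx])
}

#' Scale a contact map to a fixed total
#'
#' Multiplies all entries by one constant so that the sum over the full
#' matrix (both triangles plus the diagonal) equals `total`; with
#' `upperTriangleOnly = TRUE` the constraint is on the upper triangle
#' including the diagonal instead. Removes read-depth differences between
#' experiments.
#'
#' @param map A [ContactMap] with positive total.
#' @param total Target sum; default `1e5`.
#' @param upperTriangleOnly Constrain only the upper triangle sum.
#' @return The rescaled [ContactMap].
#' @export
normalizeTotal <- function(map, total = 1e5, upperTriangleOnly = FALSE) {
    stopifnot(is(map, "ContactMap"))
    s <- if (upperTriangleOnly) {
        sum(map@values[upper.tri(map@values, diag = TRUE)])
    } else {
        sum(map@values)
    }
    if (s <= 0) {
        stop("cannot normalize a map with non-positive total", call. = FALSE)
    }
    setMapValues(map, map@values * (total / s))
}

#' Assign experiments to train/test/validation splits
#'
#' For each assay (processed in sorted label order), that assay's observed
#' experiments are shuffled with the seeded RNG and assigned cyclically in
#' the order train, test, validation, train, test, validation, ... An
#' assay with two experiments therefore contributes one training and one
#' test map, and every assay with at least one experiment has at least one
#' training map.
#'
#' @param grid A [ContactGrid] (typically after [pruneGrid()]).
#' @param seed Integer seed; the assignment is deterministic given the
#'   seed.
#'
#' @return A data frame with columns `biosample`, `assay`, `split`
#'   (`"train"`, `"test"`, or `"validation"`) and the seed stored in
#'   `attr(, "seed")`.
#' @export
splitExperiments <- function(grid, seed) {
    keys <- observedKeys(grid)
    cycle <- c("train", "test", "validation")
    out <- withSeed(seed, {
        parts <- lapply(sort(unique(keys$assay)), function(a) {
            rows <- which(keys$assay == a)
            rows <- rows[sample.int(length(rows))]
            data.frame(biosample = keys$biosample[rows], assay = a,
                       split = cycle[(seq_along(rows) - 1L) %% 3L + 1L],
                       stringsAsFactors = FALSE)
        })
        do.call(rbind, parts)
    })
    rownames(out) <- NULL
    attr(out, "seed") <- as.integer(seed)
    out
}

# internal: keys of a split subset, as grid keys
splitKeys <- function(split, which) {
    rows <- split$split %in% which
    gridKey(split$biosample[rows], split$assay[rows])
}

#' Normalize every map of a grid
#'
#' The full preprocessing pipeline applied to an assembled grid:
#' (1) `log(x + 1)` transform every map; (2) compute a [BinMask] from the
#' *training* maps' marginals of the transformed maps
#' ([selectRetainedBins()]) and apply it to every map; (3) scale each map
#' so its entries sum to `total` ([normalizeTotal()]). Validation and test
#' maps never influence the mask.
#'
#' @param grid A [ContactGrid].
#' @param split Split assignment from [splitExperiments()] covering the
#'   grid's observed experiments.
#' @param kMad,madKind Passed to [selectRetainedBins()].
#' @param total,upperTriangleOnly Passed to [normalizeTotal()].
#'
#' @return A list with elements `grid` (the normalized [ContactGrid]) and
#'   `mask` (the [BinMask] used).
#' @export
preprocessGrid <- function(grid, split, kMad = 10,
                           madKind = c("median", "mean"), total = 1e5,
                           upperTriangleOnly = FALSE) {
    madKind <- match.arg(madKind)
    keys <- observedKeys(grid)
    obs <- gridKey(keys$biosample, keys$assay)
    lab <- gridKey(split$biosample, split$assay)
    if (!all(obs %in% lab)) {
        stop("split does not cover every observed experiment", call. = FALSE)
    }
    logged <- lapply(grid@maps, log1pMap)
    trainK <- intersect(names(logged), splitKeys(split, "train"))
    if (!length(trainK)) {
        stop("split contains no training experiments", call. = FALSE)
    }
    mask <- selectRetainedBins(logged[trainK], kMad = kMad,
                               madKind = madKind)
    grid@maps <- lapply(logged, function(m) {
        normalizeTotal(applyBinMask(m, mask), total = total,
                       upperTriangleOnly = upperTriangleOnly)
    })
    validObject(grid)
    list(grid = grid, mask = mask)
}

#' Read or write split assignments and bin masks
#'
#' Splits are persisted as CSV with columns `biosample,assay,split`; masks
#' as a one-column text file of kept original bin indices (0-based).
#'
#' @param split,mask Objects to write.
#' @param path File path.
#' @param nBins For `readBinMask`, the mask length.
#' @name split-io
NULL

#' @rdname split-io
#' @export
writeSplit <- function(split, path) {
    utils::write.csv(split[, c("biosample", "assay", "split")], path,
                     row.names = FALSE, quote = TRUE)
    invisible(path)
}

#' @rdname split-io
#' @export
readSplit <- function(path) {
    s <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("biosample", "assay", "split") %in% names(s))) {
        stop("split file must have columns biosample, assay, split",
             call. = FALSE)
    }
    bad <- setdiff(unique(s$split), c("train", "test", "validation"))
    if (length(bad)) {
        stop("unknown split labels: ", paste(bad, collapse = ", "),
             call. = FALSE)
    }
    s
}

#' @rdname split-io
#' @export
writeBinMask <- function(mask, path) {
    writeLines(as.character(keptBins(mask)), path)
    invisible(path)
}

#' @rdname split-io
#' @export
readBinMask <- function(path, nBins) {
    kept <- as.integer(readLines(path))
    keep <- rep(FALSE, nBins)
    keep[kept + 1L] <- TRUE
    new("BinMask", nBins = as.integer(nBins), keep = keep)
}
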