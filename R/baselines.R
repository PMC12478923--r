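#' @include ContactGrid-methods.R
NULL

# internal: the reference experiments for a baseline prediction.
# When a split is supplied the pool is restricted to training experiments
# (fair comparison against a model fit on the training set); without a
# split, all observed experiments qualify. The target's own map is always
# excluded.
baselinePool <- function(grid, split, biosample, assay,
                         share = c("assay", "biosample", "either")) {
    share <- match.arg(share)
    keys <- observedKeys(grid)
    if (!is.null(split)) {
        keep <- gridKey(keys$biosample, keys$assay) %in%
            splitKeys(split, "train")
        keys <- keys[keep, , drop = FALSE]
    }
    self <- keys$biosample == biosample & keys$assay == assay
    keys <- keys[!self, , drop = FALSE]
    sel <- switch(share,
        assay = keys$assay == assay,
        biosample = keys$biosample == biosample,
        either = keys$assay == assay | keys$biosample == biosample
    )
    keys[sel, , drop = FALSE]
}

meanOfMaps <- function(grid, keys, what) {
    if (!nrow(keys)) {
        stop("no reference experiments ", what, call. = FALSE)
    }
    maps <- lapply(seq_len(nrow(keys)), function(r) {
        contactValues(mapAt(grid, keys$biosample[r], keys$assay[r]))
    })
    avg <- Reduce(`+`, maps) / length(maps)
    template <- mapAt(grid, keys$biosample[1L], keys$assay[1L])
    setMapValues(template, avg)
}

#' Mean-based imputation baselines
#'
#' Three simple predictors of a missing (biosample, assay) contact map,
#' each an unweighted elementwise mean over a pool of observed maps:
#' `rowMeanImpute` averages all maps sharing the target's *assay*,
#' `columnMeanImpute` all maps sharing the target's *biosample*, and
#' `crossMeanImpute` all maps sharing either (the union of the two pools;
#' the two pools are disjoint because a map sharing both would be the
#' target itself, which is always excluded). When `split` is supplied the
#' pools are restricted to training-split experiments.
#'
#' @param grid A [ContactGrid] of (typically normalized) maps.
#' @param biosample,assay The target cell.
#' @param split Optional split assignment from [splitExperiments()]; if
#'   given, only training experiments enter the pool.
#'
#' @return A [ContactMap] prediction.
#' @examples
#' \dontrun{
#' pred <- crossMeanImpute(normGrid, "HFFc6", "micro-C", split = split)
#' }
#' @name baselines
NULL

#' @rdname baselines
#' @export
rowMeanImpute <- function(grid, biosample, assay, split = NULL) {
    keys <- baselinePool(grid, split, biosample, assay, "assay")
    meanOfMaps(grid, keys, paste0("share assay '", assay, "'"))
}

#' @rdname baselines
#' @export
columnMeanImpute <- function(grid, biosample, assay, split = NULL) {
    keys <- baselinePool(grid, split, biosample, assay, "biosample")
    meanOfMaps(grid, keys, paste0("share biosample '", biosample, "'"))
}

#' @rdname baselines
#' @export
crossMeanImpute <- function(grid, biosample, assay, split = NULL) {
    keys <- baselinePool(grid, split, biosample, assay, "either")
    meanOfMaps(grid, keys,
               paste0("share assay '", assay, "' or biosample '",
                      biosample, "'"))
}
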