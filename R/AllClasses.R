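#' ContactMap: one chromosome's binned contact matrix
#'
#' An S4 container for a single symmetric, non-negative contact matrix at a
#' fixed bin resolution, together with the bookkeeping needed to track which
#' of the chromosome's original bins are still present after bin pruning.
#' Bin indices in `retainedBins` are 0-based, and each bin `k` covers the
#' half-open genomic interval `[k * resolution, (k + 1) * resolution)`.
#'
#' @slot chrom Chromosome name.
#' @slot resolution Bin width in base pairs.
#' @slot nBinsOriginal Number of bins the chromosome had before any pruning.
#' @slot retainedBins Strictly increasing 0-based indices of the bins that
#'   index the rows/columns of `values`.
#' @slot values Square numeric matrix of contact values; exactly symmetric,
#'   finite, and non-negative unless the map holds model output (see
#'   [predictContactMap()]), in which case negativity is permitted by the
#'   constructor argument `allowNegative`.
#'
#' @seealso [ContactMap()] for construction, [readContactMap()] for file
#'   input.
#' @export
setClass("ContactMap",
    representation(
        chrom = "character",
        resolution = "integer",
        nBinsOriginal = "integer",
        retainedBins = "integer",
        values = "matrix",
        allowNegative = "logical"
    )
)

setValidity("ContactMap", function(object) {
    v <- object@values
    if (length(object@chrom) != 1L || !nzchar(object@chrom))
        return("chrom must be a single non-empty string")
    if (length(object@resolution) != 1L || object@resolution <= 0L)
        return("resolution must be a positive integer")
    if (nrow(v) != ncol(v))
        return("values must be a square matrix")
    if (!is.numeric(v))
        return("values must be numeric")
    if (length(object@retainedBins) != nrow(v))
        return("length(retainedBins) must equal the matrix side")
    rb <- object@retainedBins
    if (length(rb) && (any(diff(rb) <= 0L) || rb[1L] < 0L ||
                       rb[length(rb)] >= object@nBinsOriginal))
        return("retainedBins must be strictly increasing within [0, nBinsOriginal)")
    if (any(!is.finite(v)))
        return("values must be finite")
    if (!isTRUE(object@allowNegative) && any(v < 0))
        return("values must be non-negative")
    if (!identical(unname(v), unname(t(v))))
        return("values must be exactly symmetric")
    TRUE
})

#' ContactGrid: a biosample-by-assay collection of contact maps
#'
#' Holds the experiment grid central to the imputation problem: an ordered
#' list of biosample labels, an ordered list of assay labels, and a partial
#' mapping from (biosample, assay) pairs to [ContactMap] objects. Cells
#' without a map are the missing experiments that imputation targets. All
#' contained maps must agree on chromosome, resolution, and retained bins.
#'
#' @slot biosamples Ordered character vector of biosample labels.
#' @slot assays Ordered character vector of assay labels.
#' @slot maps Named list of [ContactMap] objects; names are internal
#'   (biosample, assay) keys.
#'
#' @seealso [assembleGrid()], [pruneGrid()], [generateGrid()]
#' @export
setClass("ContactGrid",
    representation(
        biosamples = "character",
        assays = "character",
        maps = "list"
    )
)

setValidity("ContactGrid", function(object) {
    checkLabel(object@biosamples, "biosample")
    checkLabel(object@assays, "assay")
    if (anyDuplicated(object@biosamples))
        return("duplicate biosample labels")
    if (anyDuplicated(object@assays))
        return("duplicate assay labels")
    if (length(object@maps)) {
        if (is.null(names(object@maps)) || anyDuplicated(names(object@maps)))
            return("maps must be uniquely named")
        keys <- splitGridKey(names(object@maps))
        if (!all(keys$biosample %in% object@biosamples))
            return("map biosample not in biosample list")
        if (!all(keys$assay %in% object@assays))
            return("map assay not in assay list")
        ok <- vapply(object@maps, function(m) is(m, "ContactMap"), logical(1))
        if (!all(ok))
            return("all maps must be ContactMap objects")
        ref <- object@maps[[1L]]
        same <- vapply(object@maps, function(m) {
            identical(m@chrom, ref@chrom) &&
                identical(m@resolution, ref@resolution) &&
                identical(m@retainedBins, ref@retainedBins)
        }, logical(1))
        if (!all(same))
            return("all maps must share chrom, resolution, and retained bins")
    }
    TRUE
})

#' BinMask: bins retained by training-set marginal filtering
#'
#' Records, for each original bin of the chromosome, whether it survived the
#' marginal-count filter computed on the training maps. The same mask is
#' applied to validation and test maps so that bin selection never leaks
#' information from held-out data.
#'
#' @slot nBins Number of bins the mask applies to.
#' @slot keep Logical vector of length `nBins`; `TRUE` marks a retained bin.
#'
#' @seealso [selectRetainedBins()], [applyBinMask()]
#' @export
setClass("BinMask",
    representation(nBins = "integer", keep = "logical")
)

setValidity("BinMask", function(object) {
    if (length(object@keep) != object@nBins)
        return("length(keep) must equal nBins")
    if (anyNA(object@keep))
        return("keep must not contain NA")
    if (sum(object@keep) < 2L)
        return("a BinMask must keep at least 2 bins")
    TRUE
})

#' ContactModel: embedding tables plus multilayer perceptron
#'
#' The trained (or freshly initialized) state of the deep factorization
#' model: one embedding table per input axis (biosample, assay, genomic
#' bin, and bin-pair distance), the dense layers that map the concatenated
#' embeddings to a predicted normalized contact value, the training
#' history, and the epoch whose parameters were selected by validation
#' error. Distances are raw bin separations, one embedding row per possible
#' separation `0 .. nBins - 1`.
#'
#' @slot biosamples,assays Labels the model can predict for, in embedding
#'   row order.
#' @slot nBins Number of (retained) bins the position and distance tables
#'   cover.
#' @slot hyperparams Named list, see [defaultHyperparams()].
#' @slot biosampleEmbedding,assayEmbedding,positionEmbedding,distanceEmbedding
#'   Numeric embedding tables (rows = entities, columns = factors).
#' @slot layers List of dense layers, each `list(W, b)`; hidden layers use a
#'   rectified-linear activation, the final layer is linear with a single
#'   output unit.
#' @slot conv For the convolutional position-encoder variant, the two
#'   convolution stages (`list(W1, b1, W2, b2)`); empty list for the
#'   standard model.
#' @slot variant `"mlp"` or `"conv"`.
#' @slot history Data frame with one row per epoch (epoch 0 is the random
#'   initialization): `epoch`, `trainLoss`, `validationMSE`.
#' @slot bestEpoch Epoch (>= 1) whose snapshot the slots hold after
#'   training; 0 for an untrained model.
#' @slot seed Seed used for initialization/training.
#'
#' @seealso [initContactModel()], [trainContactModel()], [forwardPass()],
#'   [predictContactMap()]
#' @export
setClass("ContactModel",
    representation(
        biosamples = "character",
        assays = "character",
        nBins = "integer",
        hyperparams = "list",
        biosampleEmbedding = "matrix",
        assayEmbedding = "matrix",
        positionEmbedding = "matrix",
        distanceEmbedding = "matrix",
        layers = "list",
        conv = "list",
        variant = "character",
        history = "data.frame",
        bestEpoch = "integer",
        seed = "integer"
    )
)

setValidity("ContactModel", function(object) {
    if (!object@variant %in% c("mlp", "conv"))
        return("variant must be 'mlp' or 'conv'")
    if (nrow(object@biosampleEmbedding) != length(object@biosamples))
        return("biosample embedding rows must match label count")
    if (nrow(object@assayEmbedding) != length(object@assays))
        return("assay embedding rows must match label count")
    if (nrow(object@positionEmbedding) != object@nBins)
        return("position embedding must have one row per bin")
    if (nrow(object@distanceEmbedding) != object@nBins)
        return("distance embedding must have one row per separation 0..nBins-1")
    TRUE
})

#' FeatureProfile: a 1D summary of one contact map
#'
#' @slot kind One of `"decay"`, `"eigenvector"`, `"insulation"`.
#' @slot values Numeric vector; for `"decay"` one value per diagonal offset,
#'   for `"eigenvector"` one value per bin (unit Euclidean norm), for
#'   `"insulation"` one value per window start.
#' @slot indexMeaning `"distance_bins"`, `"bin_position"`, or
#'   `"window_start"`.
#' @slot params Named list of the parameters used (e.g. insulation window).
#'
#' @seealso [contactDecayProfile()], [compartmentEigenvector()],
#'   [insulationScore()]
#' @export
setClass("FeatureProfile",
    representation(
        kind = "character",
        values = "numeric",
        indexMeaning = "character",
        params = "list"
    )
)

setValidity("FeatureProfile", function(object) {
    if (!object@kind %in% c("decay", "eigenvector", "insulation"))
        return("kind must be decay, eigenvector, or insulation")
    if (!object@indexMeaning %in%
            c("distance_bins", "bin_position", "window_start"))
        return("invalid indexMeaning")
    TRUE
})
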