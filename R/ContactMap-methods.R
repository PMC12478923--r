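#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a ContactMap
#'
#' @param values Square symmetric numeric matrix of contact values.
#' @param chrom Chromosome name.
#' @param resolution Bin width in base pairs.
#' @param nBinsOriginal Number of bins before pruning; defaults to
#'   `nrow(values)`.
#' @param retainedBins 0-based indices of the bins present in `values`;
#'   defaults to all bins.
#' @param allowNegative Permit negative entries (used for model
#'   predictions, which are unconstrained regression outputs).
#'
#' @return A [ContactMap] object.
#' @examples
#' m <- ContactMap(matrix(c(0, 5, 5, 0), 2), chrom = "chrS", resolution = 1e5)
#' contactValues(m)
#' @export
ContactMap <- function(values, chrom = "chrU", resolution = 100000L,
                       nBinsOriginal = nrow(values),
                       retainedBins = seq_len(nrow(values)) - 1L,
                       allowNegative = FALSE) {
    storage.mode(values) <- "double"
    dimnames(values) <- NULL
    new("ContactMap", chrom = as.character(chrom),
        resolution = as.integer(resolution),
        nBinsOriginal = as.integer(nBinsOriginal),
        retainedBins = as.integer(retainedBins),
        values = values, allowNegative = isTRUE(allowNegative))
}

#' Accessors for ContactMap
#'
#' `contactValues` returns the contact matrix, `chromName` the chromosome,
#' `binResolution` the bin width, `nBins` the current (post-pruning) bin
#' count, and `retainedBins` the 0-based original indices of those bins.
#'
#' @param x A [ContactMap].
#' @name ContactMap-accessors
#' @aliases contactValues chromName binResolution nBins retainedBins
NULL

#' @rdname ContactMap-accessors
#' @export
setMethod("contactValues", "ContactMap", function(x) x@values)

#' @rdname ContactMap-accessors
#' @export
setMethod("chromName", "ContactMap", function(x) x@chrom)

#' @rdname ContactMap-accessors
#' @export
setMethod("binResolution", "ContactMap", function(x) x@resolution)

#' @rdname ContactMap-accessors
#' @export
setMethod("nBins", "ContactMap", function(x) nrow(x@values))

#' @rdname ContactMap-accessors
#' @export
setMethod("retainedBins", "ContactMap", function(x) x@retainedBins)

setMethod("show", "ContactMap", function(object) {
    cat("ContactMap on", object@chrom, "at", object@resolution, "bp\n")
    cat("  bins:", nrow(object@values), "retained of",
        object@nBinsOriginal, "original\n")
    cat("  total contacts:", format(sum(object@values)), "\n")
})

# internal: replace the matrix, keeping bookkeeping
setMapValues <- function(map, values, allowNegative = map@allowNegative) {
    dimnames(values) <- NULL
    initialize(map, values = values, allowNegative = allowNegative)
}
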