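#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a ContactGrid
#'
#' @param biosamples Ordered character vector of biosample labels.
#' @param assays Ordered character vector of assay labels.
#' @param maps Named list of [ContactMap]s keyed internally by
#'   (biosample, assay); usually built through [assembleGrid()] or
#'   [generateGrid()] rather than directly.
#'
#' @return A [ContactGrid].
#' @export
ContactGrid <- function(biosamples, assays, maps = list()) {
    new("ContactGrid", biosamples = as.character(biosamples),
        assays = as.character(assays), maps = maps)
}

#' Accessors for ContactGrid
#'
#' `biosamples`/`assays` return the ordered label lists, `observedKeys` a
#' data frame of the (biosample, assay) pairs with a map, `nObserved` their
#' count, `mapAt` one map (error if missing), `isObserved` a logical, and
#' `setMapAt` a grid with one cell replaced or filled.
#'
#' @param x A [ContactGrid].
#' @param biosample,assay Labels of one grid cell.
#' @param value A [ContactMap] to place at the cell.
#' @name ContactGrid-accessors
NULL

#' @rdname ContactGrid-accessors
#' @export
setMethod("biosamples", "ContactGrid", function(x) x@biosamples)

#' @rdname ContactGrid-accessors
#' @export
setMethod("assays", "ContactGrid", function(x) x@assays)

#' @rdname ContactGrid-accessors
#' @export
setMethod("observedKeys", "ContactGrid", function(x) {
    if (!length(x@maps)) {
        return(data.frame(biosample = character(0), assay = character(0),
                          stringsAsFactors = FALSE))
    }
    splitGridKey(names(x@maps))
})

#' @rdname ContactGrid-accessors
#' @export
setMethod("nObserved", "ContactGrid", function(x) length(x@maps))

#' @rdname ContactGrid-accessors
#' @export
setMethod("mapAt", "ContactGrid", function(x, biosample, assay) {
    key <- gridKey(biosample, assay)
    m <- x@maps[[key]]
    if (is.null(m)) {
        stop("no observed map for biosample '", biosample, "', assay '",
             assay, "'", call. = FALSE)
    }
    m
})

#' @rdname ContactGrid-accessors
#' @export
setMethod("isObserved", "ContactGrid", function(x, biosample, assay) {
    gridKey(biosample, assay) %in% names(x@maps)
})

#' @rdname ContactGrid-accessors
#' @export
setMethod("setMapAt", "ContactGrid", function(x, biosample, assay, value) {
    stopifnot(is(value, "ContactMap"))
    if (!biosample %in% x@biosamples || !assay %in% x@assays) {
        stop("unknown biosample or assay label", call. = FALSE)
    }
    x@maps[[gridKey(biosample, assay)]] <- value
    validObject(x)
    x
})

setMethod("show", "ContactGrid", function(object) {
    total <- length(object@biosamples) * length(object@assays)
    cat("ContactGrid:", length(object@biosamples), "biosamples x",
        length(object@assays), "assays\n")
    cat("  observed:", length(object@maps), "of", total, "cells\n")
    if (length(object@maps)) {
        m <- object@maps[[1L]]
        cat("  maps:", nrow(m@values), "bins on", m@chrom, "at",
            m@resolution, "bp\n")
    }
})

# internal: iterate over observed maps
gridMaps <- function(grid) grid@maps

# internal: observed counts by biosample and assay
observedCounts <- function(grid) {
    keys <- observedKeys(grid)
    list(
        biosample = vapply(grid@biosamples,
            function(b) sum(keys$biosample == b), integer(1)),
        assay = vapply(grid@assays,
            function(a) sum(keys$assay == a), integer(1))
    )
}
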