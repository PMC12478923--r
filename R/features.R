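#' @include AllClasses.R AllGenerics.R ContactMap-methods.R
NULL

FeatureProfile <- function(kind, values, indexMeaning, params = list()) {
    new("FeatureProfile", kind = kind, values = as.numeric(values),
        indexMeaning = indexMeaning, params = params)
}

#' @rdname FeatureProfile-accessors
#' @export
setMethod("profileValues", "FeatureProfile", function(x) x@values)

#' Accessors for FeatureProfile
#'
#' @param x A [FeatureProfile].
#' @name FeatureProfile-accessors
NULL

#' @rdname FeatureProfile-accessors
#' @export
setMethod("profileKind", "FeatureProfile", function(x) x@kind)

setMethod("show", "FeatureProfile", function(object) {
    cat("FeatureProfile '", object@kind, "' (", object@indexMeaning, "), ",
        length(object@values), " values\n", sep = "")
})

#' Contact decay profile
#'
#' The mean contact value along each diagonal of the matrix: element `d+1`
#' of the profile is the mean of all entries at bin separation `d`, for
#' `d = 0 .. nBins - 1`. Captures how contact frequency falls off with
#' genomic distance.
#'
#' @param map A [ContactMap] (or plain symmetric matrix).
#' @return A [FeatureProfile] of kind `"decay"` with `nBins` values.
#' @export
contactDecayProfile <- function(map) {
    v <- if (is(map, "ContactMap")) map@values else map
    n <- nrow(v)
    d <- col(v) - row(v)
    means <- vapply(0:(n - 1L), function(k) mean(v[d == k]), numeric(1))
    FeatureProfile("decay", means, "distance_bins")
}

#' Compartment eigenvector
#'
#' The unit-norm eigenvector of the contact matrix associated with the
#' eigenvalue of largest magnitude. Its sign pattern tracks A/B chromatin
#' compartments. Because an eigenvector's sign is arbitrary, it is fixed
#' deterministically: the vector is flipped if its Pearson correlation
#' with the map's marginal-count vector is negative; if that correlation
#' is zero or undefined, the first non-zero component is made positive.
#'
#' The eigenvector is computed on the matrix as given (normalized log
#' contacts); set `observedExpected = TRUE` to first divide each diagonal
#' by its mean and correlate columns, the conventional A/B-compartment
#' pipeline.
#'
#' @param map A symmetric [ContactMap] (or matrix).
#' @param observedExpected Apply the observed/expected + correlation
#'   transform before the eigendecomposition.
#'
#' @return A [FeatureProfile] of kind `"eigenvector"`, unit Euclidean
#'   norm.
#' @export
compartmentEigenvector <- function(map, observedExpected = FALSE) {
    v <- if (is(map, "ContactMap")) map@values else map
    if (!identical(unname(v), unname(t(v)))) {
        stop("compartmentEigenvector requires a symmetric matrix",
             call. = FALSE)
    }
    marg <- rowSums(v)
    if (observedExpected) {
        n <- nrow(v)
        d <- abs(col(v) - row(v))
        expd <- vapply(0:(n - 1L), function(k) mean(v[d == k]), numeric(1))
        oe <- v / pmax(expd[d + 1L], .Machine$double.eps)
        v <- suppressWarnings(stats::cor(oe))
        v[!is.finite(v)] <- 0
        v <- (v + t(v)) / 2
    }
    dec <- eigen(v, symmetric = TRUE)
    lead <- which.max(abs(dec$values))
    vec <- dec$vectors[, lead]
    vec <- vec / sqrt(sum(vec^2))
    r <- suppressWarnings(stats::cor(vec, marg))
    if (!is.na(r) && r != 0) {
        if (r < 0) vec <- -vec
    } else {
        nz <- which(vec != 0)
        if (length(nz) && vec[nz[1L]] < 0) vec <- -vec
    }
    FeatureProfile("eigenvector", vec, "bin_position",
                   params = list(eigenvalue = dec$values[lead]))
}

#' Insulation score
#'
#' The mean of a `window x window` diagonal-anchored submatrix slid along
#' the diagonal one bin at a time: value `s` is the mean of
#' `map[s:(s+window-1), s:(s+window-1)]`, for window starts
#' `s = 1 .. nBins - window + 1`. Local dips mark insulating (TAD)
#' boundaries.
#'
#' @param map A [ContactMap] (or matrix).
#' @param window Window size in bins; default 30.
#' @return A [FeatureProfile] of kind `"insulation"` with
#'   `nBins - window + 1` values.
#' @export
insulationScore <- function(map, window = 30L) {
    v <- if (is(map, "ContactMap")) map@values else map
    n <- nrow(v)
    window <- as.integer(window)
    if (window < 1L || window > n) {
        stop("window must lie in [1, nBins]", call. = FALSE)
    }
    # summed-area table for O(1) window sums
    cum <- t(apply(apply(v, 2L, cumsum), 1L, cumsum))
    sat <- rbind(0, cbind(0, cum))
    starts <- seq_len(n - window + 1L)
    ends <- starts + window - 1L
    sums <- vapply(seq_along(starts), function(s) {
        e <- ends[s] + 1L
        a <- starts[s]
        sat[e, e] - sat[a, e] - sat[e, a] + sat[a, a]
    }, numeric(1))
    FeatureProfile("insulation", sums / (window^2), "window_start",
                   params = list(window = window))
}

# internal: dispatch by feature kind
computeFeature <- function(map, kind, window = 30L) {
    switch(kind,
        decay = contactDecayProfile(map),
        eigenvector = compartmentEigenvector(map),
        insulation = insulationScore(map, window = window),
        stop("unknown feature kind: ", kind, call. = FALSE)
    )
}

#' Write a feature profile as TSV
#'
#' Two columns (index, value) preceded by one comment line naming the
#' feature kind and its parameters.
#'
#' @param profile A [FeatureProfile].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFeatureProfile <- function(profile, path) {
    header <- sprintf("# kind=%s index=%s%s", profile@kind,
                      profile@indexMeaning,
                      if (length(profile@params$window))
                          sprintf(" window=%d", profile@params$window)
                      else "")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    utils::write.table(
        data.frame(index = seq_along(profile@values) - 1L,
                   value = profile@values),
        con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
    invisible(path)
}
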