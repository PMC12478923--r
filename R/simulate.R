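#' @include ContactGrid-methods.R
NULL

#' Specification of a synthetic contact-map grid
#'
#' Describes a biosample-by-assay grid of synthetic contact maps with
#' planted, recoverable structure. Each map's expected contact intensity
#' at bin pair (i, j) with separation d = |i - j| is the product of
#' \itemize{
#'   \item a biosample-specific power-law distance kernel
#'     `(1 + d)^(-decayExponents[b])`,
#'   \item an assay-specific distance tilt `(1 + d)^(-assayDistanceExponents[a])`
#'     (negative exponents favour long-range contacts, emulating
#'     protocol-specific contact selection),
#'   \item a compartment term: `1 + compartmentStrength[b]` when bins i
#'     and j carry the same compartment sign, `1 - compartmentStrength[b]/2`
#'     otherwise,
#'   \item a domain (TAD) term: `tadEnrichment[b]` when i and j fall in
#'     the same inter-boundary segment, 1 otherwise,
#' }
#' scaled so the structural product sums to `depth` over the full matrix
#' and then multiplied by a rank-one biosample-assay interaction
#' `exp(interactionStrength * u[b] * v[a])` (with `u`, `v` standard
#' normal, drawn from the seed). Counts are Poisson draws per unordered
#' pair, mirrored; `noise = "none"` returns the intensities themselves.
#' A random subset of cells is hidden, re-drawn until every biosample and
#' assay keeps at least two observed maps.
#'
#' @param nBiosamples,nAssays,nBins Grid dimensions.
#' @param decayExponents Positive decay exponent per biosample.
#' @param compartmentProfiles `nBins x nBiosamples` matrix of +/-1
#'   compartment signs.
#' @param compartmentStrength Per-biosample strength in [0, 1).
#' @param tadBoundaries List (per biosample) of sorted interior boundary
#'   bins (1-based first bin of each new segment).
#' @param tadEnrichment Per-biosample within-domain enrichment (>= 1).
#' @param assayDistanceExponents Per-assay distance-tilt exponent.
#' @param interactionStrength Scale of the rank-one multiplicative
#'   biosample-assay interaction (>= 0).
#' @param missingFraction Fraction of grid cells to hide, in [0, 1).
#' @param noise `"poisson"` or `"none"`.
#' @param depth Expected total counts per map (before the interaction
#'   scale).
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#'
#' @return A list of class `"syntheticGridSpec"`.
#' @export
syntheticGridSpec <- function(nBiosamples, nAssays, nBins,
                              decayExponents = rep(1, nBiosamples),
                              compartmentProfiles =
                                  matrix(1, nBins, nBiosamples),
                              compartmentStrength = rep(0, nBiosamples),
                              tadBoundaries =
                                  rep(list(integer(0)), nBiosamples),
                              tadEnrichment = rep(1, nBiosamples),
                              assayDistanceExponents = rep(0, nAssays),
                              interactionStrength = 0,
                              missingFraction = 0,
                              noise = c("poisson", "none"),
                              depth = 2e5, seed = 1L) {
    noise <- match.arg(noise)
    spec <- list(nBiosamples = as.integer(nBiosamples),
                 nAssays = as.integer(nAssays), nBins = as.integer(nBins),
                 decayExponents = decayExponents,
                 compartmentProfiles = compartmentProfiles,
                 compartmentStrength = compartmentStrength,
                 tadBoundaries = tadBoundaries,
                 tadEnrichment = tadEnrichment,
                 assayDistanceExponents = assayDistanceExponents,
                 interactionStrength = interactionStrength,
                 missingFraction = missingFraction, noise = noise,
                 depth = depth, seed = as.integer(seed))
    stopifnot(
        spec$nBiosamples >= 1L, spec$nAssays >= 1L, spec$nBins >= 2L,
        length(spec$decayExponents) == spec$nBiosamples,
        all(spec$decayExponents > 0),
        identical(dim(spec$compartmentProfiles),
                  c(spec$nBins, spec$nBiosamples)),
        all(spec$compartmentProfiles %in% c(-1, 1)),
        length(spec$compartmentStrength) == spec$nBiosamples,
        all(spec$compartmentStrength >= 0 & spec$compartmentStrength < 1),
        length(spec$tadBoundaries) == spec$nBiosamples,
        length(spec$tadEnrichment) == spec$nBiosamples,
        all(spec$tadEnrichment >= 1),
        length(spec$assayDistanceExponents) == spec$nAssays,
        spec$interactionStrength >= 0,
        spec$missingFraction >= 0, spec$missingFraction < 1,
        spec$depth > 0
    )
    class(spec) <- "syntheticGridSpec"
    spec
}

# internal: expected intensity matrix for one (biosample, assay) cell,
# before the interaction scale; normalized to sum to depth
structuralIntensity <- function(spec, b, a) {
    n <- spec$nBins
    d <- abs(col(diag(n)) - row(diag(n)))
    lambda <- (1 + d)^(-(spec$decayExponents[b] +
                             spec$assayDistanceExponents[a]))
    prof <- spec$compartmentProfiles[, b]
    same <- outer(prof, prof) > 0
    beta <- spec$compartmentStrength[b]
    lambda <- lambda * ifelse(same, 1 + beta, 1 - beta / 2)
    seg <- findInterval(seq_len(n), sort(spec$tadBoundaries[[b]]))
    sameSeg <- outer(seg, seg, `==`)
    lambda <- lambda * ifelse(sameSeg, spec$tadEnrichment[b], 1)
    lambda * (spec$depth / sum(lambda))
}

#' Generate a synthetic experiment grid
#'
#' Draws the full grid of contact maps described by a
#' [syntheticGridSpec()] and hides a random subset of cells.
#'
#' @param spec A `"syntheticGridSpec"`.
#' @return A list with `observed` (the [ContactGrid] with missing cells),
#'   `truth` (the complete grid), and `spec`.
#' @export
generateGrid <- function(spec) {
    stopifnot(inherits(spec, "syntheticGridSpec"))
    bios <- sprintf("B%02d", seq_len(spec$nBiosamples))
    asys <- sprintf("A%02d", seq_len(spec$nAssays))
    n <- spec$nBins
    withSeed(spec$seed, {
        u <- stats::rnorm(spec$nBiosamples)
        v <- stats::rnorm(spec$nAssays)
        maps <- list()
        ut <- upper.tri(diag(n), diag = TRUE)
        for (b in seq_len(spec$nBiosamples)) {
            for (a in seq_len(spec$nAssays)) {
                lambda <- structuralIntensity(spec, b, a) *
                    exp(spec$interactionStrength * u[b] * v[a])
                if (spec$noise == "poisson") {
                    vals <- matrix(0, n, n)
                    vals[ut] <- stats::rpois(sum(ut), lambda[ut])
                    vals[lower.tri(vals)] <- t(vals)[lower.tri(vals)]
                } else {
                    vals <- lambda
                }
                maps[[gridKey(bios[b], asys[a])]] <-
                    ContactMap(vals, chrom = "chrS", resolution = 100000L)
            }
        }
        truth <- ContactGrid(bios, asys, maps)
        observed <- truth
        nCells <- spec$nBiosamples * spec$nAssays
        nHide <- round(spec$missingFraction * nCells)
        if (nHide > 0) {
            ok <- FALSE
            for (try in seq_len(200L)) {
                hide <- sample(nCells, nHide)
                hb <- (hide - 1L) %% spec$nBiosamples + 1L
                ha <- (hide - 1L) %/% spec$nBiosamples + 1L
                keepCounts <- list(
                    b = spec$nAssays - tabulate(hb, spec$nBiosamples),
                    a = spec$nBiosamples - tabulate(ha, spec$nAssays))
                if (all(keepCounts$b >= 2L) && all(keepCounts$a >= 2L)) {
                    ok <- TRUE
                    break
                }
            }
            if (!ok) {
                stop("could not draw a missing pattern leaving every ",
                     "biosample and assay with >= 2 observed maps; ",
                     "lower missingFraction", call. = FALSE)
            }
            observed@maps[gridKey(bios[hb], asys[ha])] <- NULL
        }
        list(observed = observed, truth = truth, spec = spec)
    })
}

#' The pinned synthetic grid used by the acceptance analyses
#'
#' A fixed configuration exercising the full pipeline at desk scale:
#' 6 biosamples x 5 assays x 120 bins, Poisson counts at an expected
#' depth of 2e5 per map, biosample-specific decay exponents,
#' compartments and TAD boundaries, assay-specific distance tilts, a
#' rank-one multiplicative biosample-assay interaction, and 30% of cells
#' hidden. Compartment profiles and TAD boundaries are drawn from the
#' seed; the companion split seed is returned alongside.
#'
#' @param seed Integer seed controlling all randomness.
#' @return As [generateGrid()], plus `splitSeed`.
#' @export
generateAcceptanceGrid <- function(seed = 1L) {
    seed <- as.integer(seed)
    nB <- 6L; nA <- 5L; n <- 120L
    layout <- withSeed(seed + 7L, {
        profiles <- sapply(seq_len(nB), function(b) {
            signs <- numeric(0)
            s <- 1
            while (length(signs) < n) {
                signs <- c(signs, rep(s, sample(8:20, 1L)))
                s <- -s
            }
            signs[seq_len(n)]
        })
        boundaries <- lapply(seq_len(nB), function(b) {
            bnd <- cumsum(sample(10:20, 15L, replace = TRUE))
            bnd[bnd < n]
        })
        list(profiles = profiles, boundaries = boundaries)
    })
    spec <- syntheticGridSpec(
        nBiosamples = nB, nAssays = nA, nBins = n,
        decayExponents = seq(0.7, 1.4, length.out = nB),
        compartmentProfiles = layout$profiles,
        compartmentStrength = seq(0.15, 0.5, length.out = nB),
        tadBoundaries = layout$boundaries,
        tadEnrichment = seq(1.4, 2.4, length.out = nB),
        assayDistanceExponents = seq(-0.25, 0.25, length.out = nA),
        interactionStrength = 0.6,
        missingFraction = 0.3,
        noise = "poisson",
        depth = 2e5,
        seed = seed
    )
    out <- generateGrid(spec)
    out$splitSeed <- seed
    out
}
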