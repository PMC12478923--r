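# Shared fixtures and independent oracles, all built in code.

# symmetric non-negative map with Poisson-ish integer counts
randomMap <- function(n, seed, lambda = 5) {
    set.seed(seed)
    m <- matrix(rpois(n * n, lambda), n, n)
    m <- m + t(m)
    ContactMap(m, chrom = "chrT", resolution = 100000L)
}

# grid with the given observed (biosample, assay) label pairs
makeGrid <- function(pairs, nBinsMap = 4, seedBase = 100) {
    bios <- unique(pairs$biosample)
    asys <- unique(pairs$assay)
    maps <- list()
    for (r in seq_len(nrow(pairs))) {
        maps[[paste(pairs$biosample[r], pairs$assay[r], sep = "\t")]] <-
            randomMap(nBinsMap, seedBase + r)
    }
    ContactGrid(bios, asys, maps)
}

pairsDF <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(biosample = m[, 1], assay = m[, 2],
               stringsAsFactors = FALSE)
}

# brute-force elementwise mean over an explicit pool of maps
meanOracle <- function(grid, keys) {
    acc <- NULL
    for (r in seq_len(nrow(keys))) {
        v <- contactValues(mapAt(grid, keys$biosample[r], keys$assay[r]))
        acc <- if (is.null(acc)) v else acc + v
    }
    acc / nrow(keys)
}

# brute-force MSE over the upper triangle
mseOracle <- function(p, o, includeDiagonal = FALSE) {
    n <- nrow(p)
    tot <- 0
    cnt <- 0
    for (i in seq_len(n)) {
        jStart <- if (includeDiagonal) i else i + 1L
        if (jStart > n) next
        for (j in jStart:n) {
            tot <- tot + (p[i, j] - o[i, j])^2
            cnt <- cnt + 1L
        }
    }
    tot / cnt
}

# brute-force diagonal-anchored sliding-window insulation
insulationOracle <- function(v, window) {
    n <- nrow(v)
    sapply(seq_len(n - window + 1L), function(s) {
        mean(v[s:(s + window - 1L), s:(s + window - 1L)])
    })
}

# brute-force decay profile
decayOracle <- function(v) {
    n <- nrow(v)
    sapply(0:(n - 1L), function(d) {
        mean(sapply(seq_len(n - d), function(i) v[i, i + d]))
    })
}

# tiny hyperparameters for fast model tests
tinyHyperparams <- function(...) {
    defaultHyperparams(nBiosampleFactors = 4L, nAssayFactors = 6L,
                       nPositionFactors = 6L, nDistanceFactors = 6L,
                       nLayers = 2L, nNodes = 16L, epochs = 2L,
                       batchSize = 200L, batchesPerEpoch = 10L, ...)
}

# small fully observed synthetic grid, preprocessed and split, for model
# and search tests
tinyTrainingSetup <- function(seed = 5L) {
    spec <- syntheticGridSpec(
        nBiosamples = 4L, nAssays = 3L, nBins = 24L,
        decayExponents = seq(0.8, 1.2, length.out = 4),
        missingFraction = 0, noise = "poisson", depth = 3e4, seed = seed)
    grid <- generateGrid(spec)$observed
    split <- splitExperiments(grid, seed = seed)
    prep <- preprocessGrid(grid, split)
    list(grid = prep$grid, split = split, mask = prep$mask)
}
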