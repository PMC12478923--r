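test_that("mapMSE matches analytic cases and the loop oracle", {
    m <- randomMap(5, 1)
    expect_identical(mapMSE(m, m), 0)
    shifted <- ContactMap(contactValues(m) + 2.5)
    expect_equal(mapMSE(shifted, m), 2.5^2)
    for (seed in 1:5) {
        p <- contactValues(randomMap(6, seed))
        o <- contactValues(randomMap(6, seed + 50))
        expect_equal(mapMSE(p, o), mseOracle(p, o))
        expect_equal(mapMSE(p, o, includeDiagonal = TRUE),
                     mseOracle(p, o, includeDiagonal = TRUE))
    }
    expect_error(mapMSE(contactValues(randomMap(3, 1)),
                        contactValues(randomMap(4, 1))), "shapes")
})

test_that("per-distance correlation handles self, negation, constants", {
    v <- contactValues(randomMap(6, 2))
    self <- perDistanceCorrelation(v, v)
    defined <- !is.na(self)
    expect_true(any(defined))
    expect_true(all(self[defined] == 1))
    neg <- perDistanceCorrelation(v, -v)
    expect_true(all(neg[!is.na(neg)] == -1))
    # a constant diagonal in either map is undefined at that distance
    u <- v
    d <- col(u) - row(u)
    u[d == 1] <- 3
    u <- pmax(u, t(u))
    u[d == 1] <- 3
    u[d == -1] <- 3
    got <- perDistanceCorrelation(u, v)
    expect_true(is.na(got[2]))
    # the last diagonal always has a single entry, hence NA
    expect_true(is.na(perDistanceCorrelation(v, v)[6]))
})

test_that("the MSE-versus-shared-experiments regression is exact OLS", {
    split <- data.frame(
        biosample = c("b1", "b2", "b3", "b4", "b1", "b2"),
        assay = c("a1", "a1", "a1", "a2", "a2", "a3"),
        split = c(rep("train", 4), "test", "test"))
    # counts for these four synthetic test rows are known by construction
    mseTable <- data.frame(
        biosample = c("b1", "b2", "b3", "b4"),
        assay = c("a1", "a1", "a2", "a2"),
        mse = c(0.9, 0.8, 0.5, 0.3))
    fits <- mseVsSharedTraining(mseTable, split)
    expect_identical(fits$predictor,
                     c("sharedAssay", "sharedBiosample", "sharedEither"))
    # independent oracle: closed-form normal equations for one predictor
    x <- c(3, 3, 1, 1)  # training maps sharing the assay
    y <- mseTable$mse
    slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    intercept <- mean(y) - slope * mean(x)
    r2 <- 1 - sum((y - intercept - slope * x)^2) / sum((y - mean(y))^2)
    row1 <- fits[fits$predictor == "sharedAssay", ]
    expect_equal(row1$slope, slope)
    expect_equal(row1$intercept, intercept)
    expect_equal(row1$rSquared, r2)

    # perfectly linear response gives R^2 == 1
    lin <- mseTable
    lin$mse <- 2 - 0.3 * x
    expect_equal(
        suppressWarnings(mseVsSharedTraining(lin, split))[1, "rSquared"],
        1)

    # a zero-variance predictor yields an NA fit
    split0 <- split
    split0$biosample[split0$split == "train"] <- "b9"
    fits0 <- mseVsSharedTraining(mseTable, split0)
    expect_true(is.na(fits0[fits0$predictor == "sharedBiosample",
                            "rSquared"]))
    expect_error(mseVsSharedTraining(mseTable[1:2, ], split), "three")
})

test_that("hyperparameter search samples, trains, and selects the argmin", {
    setup <- tinyTrainingSetup()
    sg <- list(learningRate = c(1e-3, 1e-2), nNodes = c(8L, 16L))
    res <- hyperparameterSearch(sg, 3L, setup$grid, setup$split, seed = 2,
                                baseHyperparams =
                                    tinyHyperparams(epochs = 1L))
    expect_identical(nrow(res$table), 3L)
    expect_identical(res$nSampled, 3L)
    expect_equal(res$best$bestValidationMSE,
                 min(res$table$bestValidationMSE))
    # distinct configurations when the grid is large enough
    expect_false(any(duplicated(res$table[, c("learningRate",
                                              "nNodes")])))
    # deterministic given the seed
    res2 <- hyperparameterSearch(sg, 3L, setup$grid, setup$split, seed = 2,
                                 baseHyperparams =
                                     tinyHyperparams(epochs = 1L))
    expect_identical(res$table, res2$table)
    expect_error(hyperparameterSearch(list(nNodes = integer(0)), 2L,
                                      setup$grid, setup$split),
                 "non-empty")
    expect_error(hyperparameterSearch(list(bogus = 1:2), 2L, setup$grid,
                                      setup$split), "unknown")
})

test_that("entity correlations average per-shared-assay Pearson values", {
    maps <- list(
        "c1\tx" = randomMap(6, 11), "c2\tx" = randomMap(6, 12),
        "c1\ty" = randomMap(6, 13), "c2\ty" = randomMap(6, 14))
    grid <- ContactGrid(c("c1", "c2"), c("x", "y"), maps)
    got <- entityCorrelation(grid, "biosample", "decay")
    # brute force: decay profiles, Pearson per shared assay, then mean
    p1 <- cor(decayOracle(contactValues(maps[["c1\tx"]])),
              decayOracle(contactValues(maps[["c2\tx"]])))
    p2 <- cor(decayOracle(contactValues(maps[["c1\ty"]])),
              decayOracle(contactValues(maps[["c2\ty"]])))
    expect_equal(got$r["c1", "c2"], mean(c(p1, p2)))
    expect_identical(got$nShared["c1", "c2"], 2L)
    expect_equal(unname(diag(got$r)), c(1, 1))
    expect_true(got$imputed)

    # identical shared maps give correlation exactly 1
    maps2 <- maps
    maps2[["c2\tx"]] <- maps2[["c1\tx"]]
    maps2[["c2\ty"]] <- maps2[["c1\ty"]]
    grid2 <- ContactGrid(c("c1", "c2"), c("x", "y"), maps2)
    expect_equal(entityCorrelation(grid2, "biosample",
                                   "decay")$r["c1", "c2"], 1)

    # the assay axis swaps the roles of the two labels
    gotA <- entityCorrelation(grid, "assay", "decay")
    q1 <- cor(decayOracle(contactValues(maps[["c1\tx"]])),
              decayOracle(contactValues(maps[["c1\ty"]])))
    q2 <- cor(decayOracle(contactValues(maps[["c2\tx"]])),
              decayOracle(contactValues(maps[["c2\ty"]])))
    expect_equal(gotA$r["x", "y"], mean(c(q1, q2)))
})

test_that("pairs with no shared experiments are missing, not zero", {
    grid <- makeGrid(pairsDF("c1", "x", "c1", "y", "c2", "x",
                             "c3", "y"))
    got <- entityCorrelation(grid, "biosample", "decay")
    expect_true(is.na(got$r["c2", "c3"]))
    expect_identical(got$nShared["c2", "c3"], 0L)
    expect_false(got$imputed)
    expect_identical(unname(is.na(got$r)), unname(got$nShared == 0L))
})

test_that("hierarchical clustering merges the nearest pair first", {
    mk <- function(r) {
        structure(list(entities = colnames(r), r = r,
                       nShared = matrix(1L, nrow(r), ncol(r)),
                       feature = "decay", axis = "biosample",
                       imputed = TRUE), class = "entityCorrelation")
    }
    r <- matrix(c(1, 0.99, 0.5,
                  0.99, 1, 0.5,
                  0.5, 0.5, 1), 3,
                dimnames = list(c("e1", "e2", "e3"), c("e1", "e2", "e3")))
    hc <- clusterEntities(mk(r))
    expect_identical(sort(hc$merge[1, ]), c(-2L, -1L))
    expect_equal(hc$height[1], 1 - 0.99)

    # identical entities merge at height zero
    rid <- matrix(1, 2, 2, dimnames = list(c("u", "v"), c("u", "v")))
    expect_equal(clusterEntities(mk(rid))$height, 0)

    # four entities against an explicit hand agglomeration: repeatedly
    # merge the two clusters with the smallest mean pairwise distance
    avgLinkHeights <- function(d) {
        clusters <- as.list(seq_len(nrow(d)))
        heights <- numeric(0)
        while (length(clusters) > 1) {
            best <- NULL
            bestd <- Inf
            for (p in seq_along(clusters)) {
                for (q in seq_len(p - 1)) {
                    dd <- mean(d[clusters[[p]], clusters[[q]]])
                    if (dd < bestd) {
                        bestd <- dd
                        best <- c(q, p)
                    }
                }
            }
            heights <- c(heights, bestd)
            merged <- c(clusters[[best[1]]], clusters[[best[2]]])
            clusters <- c(clusters[-best], list(merged))
        }
        heights
    }
    set.seed(8)
    x <- matrix(rnorm(20), 4)
    r4 <- cor(t(x))
    dimnames(r4) <- list(letters[1:4], letters[1:4])
    hc4 <- clusterEntities(mk(r4))
    expect_equal(hc4$height, avgLinkHeights(1 - r4))

    rna <- r
    rna[1, 3] <- rna[3, 1] <- NA
    expect_error(clusterEntities(mk(rna)), "impute")
})

test_that("imputation does not inflate cross-seed correlation variance", {
    # the smoothing effect: correlations estimated from sparse shared
    # support fluctuate across simulated datasets at least as much as
    # their imputation-backed counterparts
    rU <- numeric(0)
    rI <- numeric(0)
    for (s in 1:12) {
        g <- generateGrid(syntheticGridSpec(
            nBiosamples = 5L, nAssays = 4L, nBins = 25L,
            decayExponents = seq(0.7, 1.3, length.out = 5),
            missingFraction = 0.35, depth = 2e4, seed = s))$observed
        partial <- entityCorrelation(g, "biosample", "decay")
        full <- completeGrid(g, method = "cross")
        imputed <- entityCorrelation(full, "biosample", "decay")
        rU <- c(rU, partial$r["B01", "B02"])
        rI <- c(rI, imputed$r["B01", "B02"])
    }
    ok <- !is.na(rU)
    expect_gte(sum(ok), 10L)
    expect_lte(var(rI[ok]), var(rU[ok]))
})
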