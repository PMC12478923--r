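test_that("ContactMap validity enforces the container invariants", {
    m <- ContactMap(matrix(c(0, 5, 5, 0), 2))
    expect_s4_class(m, "ContactMap")
    expect_identical(nBins(m), 2L)
    expect_identical(retainedBins(m), 0:1)
    expect_error(ContactMap(matrix(c(0, 1, 2, 0), 2)), "symmetric")
    expect_error(ContactMap(matrix(-1, 2, 2)), "non-negative")
    expect_error(ContactMap(matrix(c(0, Inf, Inf, 0), 2)), "finite")
    expect_error(ContactMap(matrix(0, 2, 3)), "square")
    expect_error(ContactMap(matrix(0, 2, 2), retainedBins = c(1L, 0L)),
                 "retainedBins")
})

test_that("triplet reading mirrors, sums duplicates, and zero-fills", {
    tf <- withr::local_tempfile()
    writeLines("0\t1\t5", tf)
    expect_equal(contactValues(readContactMap(tf, "triplet", 2)),
                 matrix(c(0, 5, 5, 0), 2))

    writeLines(character(0), tf)
    expect_equal(contactValues(readContactMap(tf, "triplet", 3)),
                 matrix(0, 3, 3))

    writeLines(c("0\t1\t2", "1\t0\t3", "2\t2\t7"), tf)
    expect_equal(contactValues(readContactMap(tf, "triplet", 3)),
                 matrix(c(0, 5, 0, 5, 0, 0, 0, 0, 7), 3))
})

test_that("malformed or invalid triplet input fails with the line number", {
    tf <- withr::local_tempfile()
    writeLines(c("0\t1\t5", "0\t1"), tf)
    expect_error(readContactMap(tf, "triplet", 2), "line 2")
    writeLines(c("0\t1\tx"), tf)
    expect_error(readContactMap(tf, "triplet", 2), "line 1")
    writeLines(c("0\t5\t1"), tf)
    expect_error(readContactMap(tf, "triplet", 2), "out of range")
    writeLines(c("0\t1\t-2"), tf)
    expect_error(readContactMap(tf, "triplet", 2), "negative")
})

test_that("asymmetric dense input is rejected, near-symmetric accepted", {
    tf <- withr::local_tempfile()
    m <- matrix(c(1, 2, 5, 1), 2)
    write.table(m, tf, sep = "\t", row.names = FALSE, col.names = FALSE)
    expect_error(readContactMap(tf, "dense", 2), "not symmetric")

    m <- matrix(c(1, 2, 2 + 1e-12, 1), 2)
    write.table(m, tf, sep = "\t", row.names = FALSE, col.names = FALSE)
    got <- contactValues(readContactMap(tf, "dense", 2))
    expect_identical(got, t(got))
})

test_that("read/write round trips are exact for both formats", {
    tf <- withr::local_tempfile()
    for (seed in 1:5) {
        m <- randomMap(6, seed)
        for (fmt in c("dense", "triplet")) {
            writeContactMap(m, tf, fmt)
            back <- readContactMap(tf, fmt, nBins = 6)
            expect_equal(contactValues(back), contactValues(m),
                         tolerance = 1e-9)
        }
    }
    # non-integer values survive the round trip too
    m <- ContactMap(matrix(c(0, pi, pi, exp(1)), 2))
    writeContactMap(m, tf, "triplet")
    expect_equal(contactValues(readContactMap(tf, "triplet", 2)),
                 contactValues(m), tolerance = 1e-15)
})

test_that("triplet output lists exactly the upper-triangle nonzeros", {
    tf <- withr::local_tempfile()
    m <- ContactMap(matrix(c(0, 5, 0, 5, 0, 0, 0, 0, 7), 3))
    writeContactMap(m, tf, "triplet")
    expect_identical(readLines(tf), c("0\t1\t5", "2\t2\t7"))

    writeContactMap(ContactMap(matrix(0, 3, 3)), tf, "triplet")
    expect_identical(readLines(tf), character(0))
})

test_that("assembleGrid builds the observed cells and rejects duplicates", {
    dir <- withr::local_tempdir()
    mf <- data.frame(biosample = c("b1", "b1", "b2"),
                     assay = c("a1", "a2", "a1"),
                     path = file.path(dir, paste0("m", 1:3, ".tsv")),
                     format = "triplet")
    for (r in 1:3) writeContactMap(randomMap(3, r), mf$path[r], "triplet")
    grid <- assembleGrid(mf, nBins = 3)
    expect_identical(nObserved(grid), 3L)
    expect_identical(biosamples(grid), c("b1", "b2"))
    expect_true(isObserved(grid, "b1", "a2"))
    expect_false(isObserved(grid, "b2", "a2"))

    expect_error(assembleGrid(rbind(mf, mf[1, ]), nBins = 3), "duplicate")
    mf$path[2] <- file.path(dir, "missing.tsv")
    expect_error(assembleGrid(mf, nBins = 3), "b1.*a2|a2.*b1")
})

test_that("a 41-of-88 observed pattern leaves 47 missing cells", {
    pairs <- expand.grid(biosample = sprintf("c%02d", 1:11),
                         assay = sprintf("y%d", 1:8),
                         stringsAsFactors = FALSE)
    set.seed(41)
    # keep drawing until the observed pattern survives pruning intact
    repeat {
        obs <- pairs[sample(88, 41), ]
        counts <- list(table(obs$biosample), table(obs$assay))
        if (length(counts[[1]]) == 11 && length(counts[[2]]) == 8 &&
                all(unlist(counts) >= 2)) break
    }
    grid <- makeGrid(obs, nBinsMap = 2)
    expect_identical(nObserved(grid), 41L)
    expect_identical(length(biosamples(grid)) * length(assays(grid)) -
                         nObserved(grid), 47L)
    expect_identical(nObserved(pruneGrid(grid)), 41L)
})

test_that("pruneGrid applies the iterative >= 2 support rule", {
    # remove assay Z (1 entry), then biosample C (0 entries)
    grid <- makeGrid(pairsDF("A", "X", "A", "Y", "B", "X", "B", "Y",
                             "C", "Z"))
    pruned <- pruneGrid(grid)
    expect_setequal(biosamples(pruned), c("A", "B"))
    expect_setequal(assays(pruned), c("X", "Y"))
    expect_identical(nObserved(pruned), 4L)

    # already-valid grid is a fixed point
    ok <- makeGrid(pairsDF("A", "X", "A", "Y", "B", "X", "B", "Y"))
    expect_identical(observedKeys(pruneGrid(ok)), observedKeys(ok))

    # single observed cell collapses to nothing
    expect_error(pruneGrid(makeGrid(pairsDF("A", "X"))), "empty")
})

test_that("pruneGrid is invariant to manifest row order and monotone", {
    set.seed(7)
    for (rep in 1:10) {
        nb <- sample(3:6, 1)
        na <- sample(3:6, 1)
        pairs <- expand.grid(biosample = sprintf("b%d", seq_len(nb)),
                             assay = sprintf("a%d", seq_len(na)),
                             stringsAsFactors = FALSE)
        pairs <- pairs[runif(nrow(pairs)) < 0.45, , drop = FALSE]
        if (nrow(pairs) < 2) next
        grid1 <- makeGrid(pairs)
        perm <- pairs[sample(nrow(pairs)), , drop = FALSE]
        grid2 <- makeGrid(perm)
        res <- lapply(list(grid1, grid2), function(g) {
            tryCatch(pruneGrid(g), error = function(e) "empty")
        })
        if (identical(res[[1]], "empty")) {
            expect_identical(res[[2]], "empty")
        } else {
            k1 <- observedKeys(res[[1]])
            k2 <- observedKeys(res[[2]])
            expect_setequal(paste(k1$biosample, k1$assay),
                            paste(k2$biosample, k2$assay))
            # no observed count ever increases
            for (b in biosamples(res[[1]])) {
                expect_lte(sum(observedKeys(res[[1]])$biosample == b),
                           sum(pairs$biosample == b))
            }
        }
    }
})

test_that("writeGrid round trips through a manifest", {
    dir <- withr::local_tempdir()
    grid <- makeGrid(pairsDF("A", "X", "A", "Y", "B", "X", "B", "Y"))
    writeGrid(grid, dir, format = "triplet")
    back <- assembleGrid(file.path(dir, "manifest.csv"), nBins = 4)
    expect_setequal(names(back@maps), names(grid@maps))
    for (k in names(grid@maps)) {
        expect_equal(contactValues(back@maps[[k]]),
                     contactValues(grid@maps[[k]]), tolerance = 1e-9)
    }
})
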