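#' @include ContactMap-methods.R ContactGrid-methods.R
NULL

#' Read a binned contact map from a text file
#'
#' Two plain-text layouts are supported. `"dense"` is a tab-separated
#' `nBins` x `nBins` numeric matrix with no header; the input must be
#' symmetric to within `1e-8` relative tolerance and is exactly symmetrized
#' on read. `"triplet"` is a sparse bin-pair list with tab-separated rows
#' `bin1 bin2 count` (0-based bin indices); each row is mirrored across the
#' diagonal, duplicate rows for the same unordered pair are summed, and
#' unlisted pairs are zero.
#'
#' @param path Path to the file.
#' @param format `"dense"` or `"triplet"`.
#' @param nBins Number of bins of the chromosome at this resolution.
#' @param resolution Bin width in base pairs.
#' @param chrom Chromosome name to record.
#' @param allowNegative Accept negative values (model predictions written
#'   with [writeContactMap()] are unconstrained regression outputs).
#'
#' @return A [ContactMap] with all bins retained.
#' @examples
#' tf <- tempfile()
#' writeLines("0\t1\t5", tf)
#' m <- readContactMap(tf, "triplet", nBins = 2)
#' contactValues(m)   # matrix(c(0, 5, 5, 0), 2)
#' @export
readContactMap <- function(path, format = c("dense", "triplet"), nBins,
                           resolution = 100000L, chrom = "chrU",
                           allowNegative = FALSE) {
    format <- match.arg(format)
    if (!file.exists(path)) {
        stop("contact map file not found: ", path, call. = FALSE)
    }
    nBins <- as.integer(nBins)
    if (format == "dense") {
        values <- readDenseMatrix(path, nBins)
    } else {
        values <- readTripletMatrix(path, nBins)
    }
    if (!allowNegative && any(values < 0)) {
        stop("negative contact count in ", path, call. = FALSE)
    }
    ContactMap(values, chrom = chrom, resolution = resolution,
               nBinsOriginal = nBins, allowNegative = allowNegative)
}

readDenseMatrix <- function(path, nBins) {
    dt <- tryCatch(
        data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "numeric", data.table = FALSE),
        error = function(e) {
            stop("parse error in dense contact map ", path, ": ",
                 conditionMessage(e), call. = FALSE)
        }
    )
    values <- as.matrix(dt)
    if (nrow(values) != nBins || ncol(values) != nBins) {
        stop("dense contact map ", path, " is ", nrow(values), "x",
             ncol(values), ", expected ", nBins, "x", nBins, call. = FALSE)
    }
    if (anyNA(values) || any(!is.finite(values))) {
        stop("non-finite entries in dense contact map ", path, call. = FALSE)
    }
    asym <- max(abs(values - t(values)))
    scale <- max(abs(values), 1e-12)
    if (asym > 1e-8 * scale) {
        stop("dense contact map ", path, " is not symmetric (relative ",
             "asymmetry ", format(asym / scale), ")", call. = FALSE)
    }
    (values + t(values)) / 2
}

readTripletMatrix <- function(path, nBins) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    values <- matrix(0, nBins, nBins)
    if (!length(lines)) {
        return(values)
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 3L)
    if (length(bad)) {
        stop("parse error in triplet file ", path, " at line ", bad[1L],
             ": expected 3 tab-separated fields", call. = FALSE)
    }
    fields <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
    i <- suppressWarnings(as.integer(fields[, 1L]))
    j <- suppressWarnings(as.integer(fields[, 2L]))
    count <- suppressWarnings(as.numeric(fields[, 3L]))
    bad <- which(is.na(i) | is.na(j) | is.na(count) | !is.finite(count))
    if (length(bad)) {
        stop("parse error in triplet file ", path, " at line ", bad[1L],
             ": non-numeric field", call. = FALSE)
    }
    bad <- which(i < 0L | i >= nBins | j < 0L | j >= nBins)
    if (length(bad)) {
        stop("parse error in triplet file ", path, " at line ", bad[1L],
             ": bin index out of range [0, ", nBins, ")", call. = FALSE)
    }
    # accumulate over unordered pairs, then mirror
    lo <- pmin(i, j) + 1L
    hi <- pmax(i, j) + 1L
    acc <- Matrix::sparseMatrix(i = lo, j = hi, x = count,
                                dims = c(nBins, nBins))
    upper <- as.matrix(acc)
    values <- upper + t(upper)
    diag(values) <- diag(upper)
    values
}

#' Write a contact map to a text file
#'
#' The inverse of [readContactMap()]: `"dense"` writes the full matrix as
#' tab-separated text; `"triplet"` writes one row per non-zero
#' upper-triangle entry (diagonal included). Values are written with enough
#' digits that a read/write round trip reproduces the map to within `1e-9`
#' relative error (exactly, for values representable in decimal).
#'
#' @param map A [ContactMap].
#' @param path Output path.
#' @param format `"dense"` or `"triplet"`.
#'
#' @return `path`, invisibly.
#' @export
writeContactMap <- function(map, path, format = c("dense", "triplet")) {
    format <- match.arg(format)
    stopifnot(is(map, "ContactMap"))
    values <- map@values
    con <- tryCatch(file(path, "w"), error = function(e) {
        stop("cannot open ", path, " for writing: ", conditionMessage(e),
             call. = FALSE)
    })
    on.exit(close(con))
    if (format == "dense") {
        txt <- apply(values, 1L, function(r) {
            paste(sprintf("%.17g", r), collapse = "\t")
        })
        writeLines(txt, con)
    } else {
        idx <- which(upper.tri(values, diag = TRUE) & values != 0,
                     arr.ind = TRUE)
        if (nrow(idx)) {
            ord <- order(idx[, 1L], idx[, 2L])
            idx <- idx[ord, , drop = FALSE]
            txt <- sprintf("%d\t%d\t%.17g", idx[, 1L] - 1L, idx[, 2L] - 1L,
                           values[idx])
            writeLines(txt, con)
        }
    }
    invisible(path)
}

#' Read an experiment manifest
#'
#' A manifest is a CSV file with header `biosample,assay,path,format`
#' listing one contact-map file per observed experiment. Relative `path`
#' entries are resolved against the manifest's directory.
#'
#' @param path Path to the manifest CSV.
#' @return A data frame with columns `biosample`, `assay`, `path`,
#'   `format`.
#' @export
readManifest <- function(path) {
    mf <- utils::read.csv(path, stringsAsFactors = FALSE)
    required <- c("biosample", "assay", "path", "format")
    missing <- setdiff(required, names(mf))
    if (length(missing)) {
        stop("manifest ", path, " is missing columns: ",
             paste(missing, collapse = ", "), call. = FALSE)
    }
    rel <- !grepl("^(/|[A-Za-z]:)", mf$path)
    mf$path[rel] <- file.path(dirname(path), mf$path[rel])
    mf
}

#' Assemble an experiment grid from a manifest
#'
#' Loads every contact map listed in the manifest and arranges them into a
#' biosample-by-assay [ContactGrid]. Label lists follow first appearance in
#' manifest order; cells not listed are missing.
#'
#' @param manifest Data frame with columns `biosample`, `assay`, `path`,
#'   `format` (as returned by [readManifest()]), or a path to such a CSV.
#' @param nBins,resolution,chrom,allowNegative Passed to
#'   [readContactMap()] for every file.
#'
#' @return A [ContactGrid].
#' @export
assembleGrid <- function(manifest, nBins, resolution = 100000L,
                         chrom = "chrU", allowNegative = FALSE) {
    if (is.character(manifest)) {
        manifest <- readManifest(manifest)
    }
    keys <- gridKey(manifest$biosample, manifest$assay)
    if (anyDuplicated(keys)) {
        dup <- keys[duplicated(keys)][1L]
        stop("duplicate (biosample, assay) pair in manifest: ",
             gsub("\t", " / ", dup), call. = FALSE)
    }
    maps <- vector("list", nrow(manifest))
    names(maps) <- keys
    for (r in seq_len(nrow(manifest))) {
        maps[[r]] <- tryCatch(
            readContactMap(manifest$path[r], manifest$format[r], nBins,
                           resolution, chrom, allowNegative),
            error = function(e) {
                stop("failed to load map for biosample '",
                     manifest$biosample[r], "', assay '", manifest$assay[r],
                     "': ", conditionMessage(e), call. = FALSE)
            }
        )
    }
    ContactGrid(unique(manifest$biosample), unique(manifest$assay), maps)
}

#' Prune sparsely observed biosamples and assays from a grid
#'
#' Iteratively removes any biosample or assay with at most one observed
#' map (deleting its maps, which can drop other counts below two) until
#' every remaining biosample and assay has at least two observed maps. The
#' fixed point does not depend on removal order.
#'
#' @param grid A [ContactGrid].
#' @return The pruned [ContactGrid].
#' @export
pruneGrid <- function(grid) {
    repeat {
        counts <- observedCounts(grid)
        dropB <- names(counts$biosample)[counts$biosample <= 1L]
        dropA <- names(counts$assay)[counts$assay <= 1L]
        if (!length(dropB) && !length(dropA)) {
            break
        }
        keys <- observedKeys(grid)
        keep <- !(keys$biosample %in% dropB | keys$assay %in% dropA)
        grid@maps <- grid@maps[keep]
        grid@biosamples <- setdiff(grid@biosamples, dropB)
        grid@assays <- setdiff(grid@assays, dropA)
        if (!length(grid@biosamples) || !length(grid@assays) ||
                !length(grid@maps)) {
            stop("grid prunes to empty: no biosample/assay combination ",
                 "has the required support", call. = FALSE)
        }
    }
    validObject(grid)
    grid
}

#' Write a grid as map files plus a manifest
#'
#' Writes every observed map under `dir` and a `manifest.csv` referencing
#' them, so the grid can be reloaded with [assembleGrid()].
#'
#' @param grid A [ContactGrid].
#' @param dir Output directory (created if needed).
#' @param format File format for the maps, see [writeContactMap()].
#' @return The manifest path, invisibly.
#' @export
writeGrid <- function(grid, dir, format = c("triplet", "dense")) {
    format <- match.arg(format)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    keys <- observedKeys(grid)
    fname <- sprintf("map_%s_%s.tsv",
                     gsub("[^A-Za-z0-9._-]", "_", keys$biosample),
                     gsub("[^A-Za-z0-9._-]", "_", keys$assay))
    if (anyDuplicated(fname)) {
        fname <- sprintf("map_%03d.tsv", seq_len(nrow(keys)))
    }
    for (r in seq_len(nrow(keys))) {
        writeContactMap(mapAt(grid, keys$biosample[r], keys$assay[r]),
                        file.path(dir, fname[r]), format)
    }
    manifest <- data.frame(biosample = keys$biosample, assay = keys$assay,
                           path = fname, format = format,
                           stringsAsFactors = FALSE)
    mpath <- file.path(dir, "manifest.csv")
    utils::write.csv(manifest, mpath, row.names = FALSE, quote = TRUE)
    invisible(mpath)
}
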