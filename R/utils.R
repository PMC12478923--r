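# internal helpers shared across the package

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded operations do not perturb the session stream.
withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) {
            assign(".Random.seed", old, envir = globalenv())
        } else {
            suppressWarnings(rm(".Random.seed", envir = globalenv()))
        }
    }, add = TRUE)
    set.seed(as.integer(seed))
    force(code)
}

# Key used to index maps inside a ContactGrid. Labels are free strings but
# may not contain the separator characters.
gridKey <- function(biosample, assay) {
    paste(biosample, assay, sep = "\t")
}

splitGridKey <- function(key) {
    parts <- strsplit(key, "\t", fixed = TRUE)
    data.frame(
        biosample = vapply(parts, `[`, character(1), 1L),
        assay = vapply(parts, `[`, character(1), 2L),
        stringsAsFactors = FALSE
    )
}

checkLabel <- function(x, what) {
    if (!is.character(x) || any(!nzchar(x)) || anyNA(x)) {
        stop(what, " labels must be non-empty strings", call. = FALSE)
    }
    if (any(grepl("[\t\n]", x))) {
        stop(what, " labels may not contain tab or newline characters",
             call. = FALSE)
    }
    invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
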