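`%||%` <- function(a, b) if (is.null(a)) b else a

# Uppercase, whitespace-trimmed gene symbol normalization.  No alias
# mapping is attempted; an optional synonym table (old -> new) may be
# applied after normalization.
normalizeSymbols <- function(x, synonyms = NULL) {
    out <- toupper(trimws(x))
    if (!is.null(synonyms)) {
        stopifnot(is.character(synonyms), !is.null(names(synonyms)))
        key <- toupper(trimws(names(synonyms)))
        val <- toupper(trimws(synonyms))
        hit <- match(out, key)
        out[!is.na(hit)] <- val[hit[!is.na(hit)]]
    }
    out
}

# Canonical unordered-pair key "A|B" with A <= B.
pairKey <- function(a, b) {
    lo <- ifelse(a <= b, a, b)
    hi <- ifelse(a <= b, b, a)
    paste(lo, hi, sep = "|")
}

assertScalarNumber <- function(x, name, min = -Inf, max = Inf) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
        stop(sprintf("'%s' must be a single number in [%s, %s]", name,
            format(min), format(max)), call. = FALSE)
    invisible(x)
}

# All simulators run under withr::with_seed so a given seed reproduces a
# dataset exactly without disturbing the caller's RNG stream.
withSeed <- function(seed, code) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("'seed' must be a single integer", call. = FALSE)
    withr::with_seed(as.integer(seed), code)
}
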