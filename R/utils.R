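# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL means "use the current stream".
withSeed <- function(seed, code) {
    if (is.null(seed)) return(force(code))
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        set.seed(NULL)
    }
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    force(code)
}

# Named substream seeds derived from one root seed; kept inside 32-bit range.
deriveSeed <- function(seed, k) {
    as.integer((as.numeric(seed) %% 65521) * 31687 + 7919 * k) %% 2147483629L
}

# Centered moving average with partial windows at the edges (no NA padding).
movingAverage <- function(x, width) {
    width <- as.integer(width)
    if (width <= 1L) return(x)
    half <- width %/% 2L
    n <- length(x)
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# 17 significant digits: doubles survive a write/read round trip exactly
fmtNum <- function(x) sprintf("%.17g", x)

isCount <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x >= 0 && abs(x - round(x)) < 1e-8

stopIfNot <- function(cond, msg, ...) {
    if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}
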