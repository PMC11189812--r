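# Independent oracles used across tests. These deliberately avoid the code
# paths they check: covariance by explicit loops, event filtering by literal
# rule application, Spearman by the average-rank formula.

# unbiased covariance via explicit loops (no stats::cov)
bruteCov <- function(x) {
    n <- nrow(x); p <- ncol(x)
    mu <- colSums(x) / n
    S <- matrix(0, p, p)
    for (i in seq_len(n)) {
        d <- x[i, ] - mu
        S <- S + outer(d, d)
    }
    S / (n - 1)
}

# brute-force forward-model pattern A = S W / (W' S W)
bruteActivation <- function(x, w) {
    S <- bruteCov(x)
    s <- 0
    for (j in seq_along(w)) for (k in seq_along(w))
        s <- s + w[j] * S[j, k] * w[k]
    drop(S %*% w) / s
}

# literal application of the nonsequential rule against the full log
bruteNonseqFilter <- function(ev, gap = 10) {
    keep <- logical(nrow(ev))
    for (i in seq_len(nrow(ev))) {
        keep[i] <- if (i == 1L) TRUE else ev$onset[i] - ev$offset[i - 1L] >= gap
    }
    ev[keep, , drop = FALSE]
}

# random non-overlapping onset-ordered event log
randomEventLog <- function(n, maxGap = 25) {
    dur <- stats::runif(n, 0.5, 6)
    gaps <- stats::runif(n, 0, maxGap)
    onset <- cumsum(gaps) + cumsum(c(0, dur[-n]))
    data.frame(onset = onset, offset = onset + dur,
               label = sample(c("mouse", "object"), n, replace = TRUE))
}

# Spearman rho from average ranks, written out
bruteSpearman <- function(a, b) {
    ra <- rank(a); rb <- rank(b)
    sum((ra - mean(ra)) * (rb - mean(rb))) /
        sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# two-group features with a planted separation so the SVM weight is nonzero
separatedProblem <- function(n, p, sep = 1.5) {
    y <- rep(c("a", "b"), each = n / 2)
    x <- matrix(stats::rnorm(n * p), n, p)
    x[y == "b", 1] <- x[y == "b", 1] + sep
    list(x = x, y = y)
}

# exact whitening: sample covariance of the result is the identity
whiten <- function(x) {
    xc <- scale(x, scale = FALSE)
    R <- chol(bruteCov(xc))
    xc %*% solve(R)
}

# ZTrace built directly from a z signal whose baseline segment is
# standardized; used where tests need full control of the session samples
makeZTrace <- function(sessionZ, rate = 100, nBaseline = 500, seed = 1) {
    zb <- withr::with_seed(seed, stats::rnorm(nBaseline))
    zb <- as.numeric(scale(zb))
    z <- c(zb, sessionZ)
    tm <- (seq_along(z) - 1) / rate
    new("ZTrace", time = tm, z = z, rate = rate,
        baselineWindow = c(0, nBaseline / rate),
        baselineMean = 0, baselineSD = 1, smoothWindow = 0)
}
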