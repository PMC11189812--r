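# Baseline correction, optional smoothing, and baseline-period z-scoring.

#' Correct a trace and z-score it to its baseline period
#'
#' Subtracts a fitted slow baseline from the raw fluorescence, optionally
#' applies a centered moving average, and standardizes the result by the mean
#' and SD of the designated home-cage baseline segment, so the baseline
#' segment of the returned trace has mean 0 and SD 1 exactly (to numerical
#' precision). Smoothing, when requested, happens before the standardization
#' constants are taken, so the exactness is preserved.
#'
#' @param trace a \linkS4class{PhotometryTrace}.
#' @param fit a \linkS4class{BaselineFit} from \code{\link{airplsBaseline}},
#'   or NULL for no baseline correction (drift-free recordings).
#' @param smoothWindow centered moving-average width in seconds; 0 (default)
#'   disables smoothing so window algebra downstream is exact.
#' @return a \linkS4class{ZTrace}.
#' @examples
#' ses <- simPhotometrySession(photoSimConfig(baselineMinutes = 1,
#'                                            sessionSeconds = 60,
#'                                            nEventsPerLabel = 2))
#' fit <- airplsBaseline(ses$trace@signal)
#' zt <- correctAndZscore(ses$trace, fit)
#' @export
correctAndZscore <- function(trace, fit = NULL, smoothWindow = 0) {
    stopIfNot(is(trace, "PhotometryTrace"),
              "trace must be a PhotometryTrace")
    corrected <- trace@signal
    if (!is.null(fit)) {
        stopIfNot(is(fit, "BaselineFit"), "fit must be a BaselineFit")
        stopIfNot(length(baseline(fit)) == length(corrected),
                  "baseline length (%d) does not match the trace (%d)",
                  length(baseline(fit)), length(corrected))
        corrected <- corrected - baseline(fit)
    }
    if (smoothWindow > 0) {
        width <- max(1L, round(smoothWindow * trace@rate))
        if (width %% 2L == 0L) width <- width + 1L   # keep it centered
        corrected <- movingAverage(corrected, width)
    }
    idx <- trace@time >= trace@baselineWindow[1] &
        trace@time < trace@baselineWindow[2]
    stopIfNot(sum(idx) >= 2L, "baseline segment has fewer than 2 samples")
    mu <- mean(corrected[idx])
    sdv <- stats::sd(corrected[idx])
    if (sdv <= 0)
        stop("degenerate baseline segment: zero SD after correction",
             call. = FALSE)
    new("ZTrace", time = trace@time, z = (corrected - mu) / sdv,
        rate = trace@rate, baselineWindow = trace@baselineWindow,
        baselineMean = mu, baselineSD = sdv, smoothWindow = smoothWindow)
}
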