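# Selection of nonsequential investigation events.

#' Select nonsequential investigation events
#'
#' Keeps an event when it is the first of the session or when its onset is at
#' least \code{minGap} seconds after the end (offset) of the immediately
#' preceding event \emph{in the full log} (not the filtered log). The
#' boundary is inclusive: a gap of exactly \code{minGap} keeps the event.
#' Order is preserved, and the filter is idempotent.
#'
#' @param log an \linkS4class{EventLog} (onset-ordered, non-overlapping; both
#'   enforced by the class validity).
#' @param minGap minimum offset-to-onset gap in seconds (default 10).
#' @return the filtered \linkS4class{EventLog}.
#' @examples
#' log <- EventLog(data.frame(onset = c(0, 12, 30), offset = c(5, 14, 31),
#'                            label = "mouse"))
#' events(selectNonsequentialEvents(log))   # drops the 12 s event (gap 7 s)
#' @export
selectNonsequentialEvents <- function(log, minGap = 10) {
    stopIfNot(is(log, "EventLog"), "log must be an EventLog")
    stopIfNot(is.numeric(minGap) && minGap >= 0, "minGap must be >= 0")
    ev <- events(log)
    n <- nrow(ev)
    if (n <= 1L) return(log)
    keep <- c(TRUE, ev$onset[-1L] - ev$offset[-n] >= minGap)
    EventLog(ev[keep, , drop = FALSE])
}
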