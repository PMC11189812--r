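# Contact-evoked response quantification and session statistics.

# onset aligned to the nearest sample; pre-window excludes the onset sample,
# post-window includes it (half-open windows [-w, 0) and [0, +w)).
eventWindows <- function(z, onset, window) {
    nw <- round(window * z@rate)
    i0 <- round((onset - z@time[1L]) * z@rate) + 1L
    list(pre = (i0 - nw):(i0 - 1L), post = i0:(i0 + nw - 1L),
        ok = i0 - nw >= 1L && i0 + nw - 1L <= length(z@z))
}

#' Evoked response of a single event
#'
#' The contact-evoked response is
#' \deqn{\Delta z = \mathrm{mean}\, z[0, +w) - \mathrm{mean}\, z[-w, 0),}
#' the mean z-score over the w = 3 s after contact onset minus the mean over
#' the 3 s before it. Windows are aligned to the nearest sample; the
#' pre-window excludes the onset sample and the post-window includes it.
#'
#' @param z a \linkS4class{ZTrace}.
#' @param onset event onset in seconds.
#' @param window half-window width in seconds (default 3).
#' @return the scalar evoked response, or NA (with a warning) when either
#'   window is truncated by the recording edge.
#' @export
evokedResponse <- function(z, onset, window = 3) {
    stopIfNot(is(z, "ZTrace"), "z must be a ZTrace")
    wi <- eventWindows(z, onset, window)
    if (!wi$ok) {
        warning(sprintf("event at %.2f s skipped: window truncated", onset))
        return(NA_real_)
    }
    mean(z@z[wi$post]) - mean(z@z[wi$pre])
}

#' Evoked responses for a whole event log
#'
#' Applies \code{\link{evokedResponse}} to every event of the log; events
#' whose windows are truncated by the recording edge are skipped (not
#' zero-padded) and counted.
#'
#' @param z a \linkS4class{ZTrace}.
#' @param log an \linkS4class{EventLog}, typically already filtered with
#'   \code{\link{selectNonsequentialEvents}}.
#' @param window half-window width in seconds.
#' @return an \linkS4class{EvokedResponseSet} with per-event dz and contact
#'   durations.
#' @examples
#' ses <- simPhotometrySession(photoSimConfig(baselineMinutes = 1,
#'                                            sessionSeconds = 120,
#'                                            nEventsPerLabel = 3))
#' zt <- correctAndZscore(ses$trace, airplsBaseline(ses$trace@signal))
#' evokedResponses(zt, selectNonsequentialEvents(ses$events))
#' @export
evokedResponses <- function(z, log, window = 3) {
    stopIfNot(is(log, "EventLog"), "log must be an EventLog")
    ev <- events(log)
    dz <- numeric(nrow(ev))
    ok <- logical(nrow(ev))
    for (i in seq_len(nrow(ev))) {
        wi <- eventWindows(z, ev$onset[i], window)
        ok[i] <- wi$ok
        dz[i] <- if (wi$ok) mean(z@z[wi$post]) - mean(z@z[wi$pre]) else NA_real_
    }
    if (any(!ok))
        warning(sprintf("%d event(s) skipped: window truncated by recording edge",
                        sum(!ok)))
    res <- data.frame(label = ev$label[ok], onset = ev$onset[ok],
                      offset = ev$offset[ok],
                      duration = ev$offset[ok] - ev$onset[ok],
                      dz = dz[ok])
    new("EvokedResponseSet", responses = res, skipped = sum(!ok),
        window = window)
}

#' Peri-event z-score matrix
#'
#' Extracts the z-trace around every event onset into an events x samples
#' matrix (for event-triggered averages and plotting). Truncated events are
#' dropped.
#'
#' @param z a \linkS4class{ZTrace}.
#' @param log an \linkS4class{EventLog}.
#' @param window c(before, after) in seconds, default c(-3, 3).
#' @return numeric matrix with one row per analysable event; column names are
#'   times relative to onset.
#' @export
periEventMatrix <- function(z, log, window = c(-3, 3)) {
    ev <- events(log)
    nPre <- round(-window[1] * z@rate)
    nPost <- round(window[2] * z@rate)
    rel <- ((-nPre):(nPost - 1L)) / z@rate
    rows <- list()
    for (i in seq_len(nrow(ev))) {
        i0 <- round((ev$onset[i] - z@time[1L]) * z@rate) + 1L
        idx <- (i0 - nPre):(i0 + nPost - 1L)
        if (idx[1L] >= 1L && idx[length(idx)] <= length(z@z))
            rows[[length(rows) + 1L]] <- z@z[idx]
    }
    m <- do.call(rbind, rows)
    if (is.null(m)) m <- matrix(numeric(0), ncol = length(rel))
    colnames(m) <- fmtNum(rel)
    m
}

#' Session-level evoked summary and paired contrast
#'
#' Averages per-event evoked responses into one mean per animal and stimulus
#' label, then contrasts the two labels (mouse vs object by default) across
#' animals with a two-sided paired t test. All-zero paired differences give
#' t = 0, p = 1; constant nonzero differences have no defined t statistic and
#' are flagged degenerate instead of returning infinities.
#'
#' @param responses either a data.frame with columns \code{animal},
#'   \code{label}, \code{dz} (one row per event) or a named list of
#'   \linkS4class{EvokedResponseSet} objects, one per animal.
#' @param labels the two labels to contrast, \code{c(test, reference)}.
#' @return list with \code{perAnimal} (animal x label mean dz),
#'   \code{meanDiff}, \code{t}, \code{df}, \code{p}, \code{degenerate},
#'   \code{n}.
#' @export
sessionEvokedSummary <- function(responses, labels = c("mouse", "object")) {
    if (is.list(responses) && !is.data.frame(responses)) {
        stopIfNot(!is.null(names(responses)),
                  "list input must be named by animal")
        responses <- do.call(rbind, lapply(names(responses), function(a) {
            r <- events(responses[[a]])
            if (!nrow(r)) return(NULL)
            data.frame(animal = a, label = r$label, dz = r$dz)
        }))
    }
    stopIfNot(is.data.frame(responses) &&
              all(c("animal", "label", "dz") %in% colnames(responses)),
              "responses must have columns animal, label, dz")
    responses <- responses[responses$label %in% labels, , drop = FALSE]
    per <- tapply(responses$dz, list(responses$animal, responses$label), mean)
    stopIfNot(all(labels %in% colnames(per)),
              "label(s) absent from the responses: %s",
              paste(setdiff(labels, colnames(per)), collapse = ", "))
    missing <- rownames(per)[rowSums(is.na(per[, labels, drop = FALSE])) > 0]
    if (length(missing))
        stop(sprintf("unpaired labels for animal(s): %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
    stopIfNot(nrow(per) >= 2L, "need >= 2 paired animals, got %d", nrow(per))
    d <- per[, labels[1]] - per[, labels[2]]
    degenerate <- FALSE
    if (stats::sd(d) == 0) {
        if (all(d == 0)) {
            tt <- list(statistic = 0, parameter = length(d) - 1L, p.value = 1)
        } else {
            degenerate <- TRUE
            tt <- list(statistic = NA_real_, parameter = length(d) - 1L,
                       p.value = NA_real_)
        }
    } else {
        tt <- stats::t.test(d)
    }
    list(perAnimal = per, meanDiff = mean(d),
         t = as.numeric(tt$statistic), df = as.numeric(tt$parameter),
         p = as.numeric(tt$p.value), degenerate = degenerate, n = nrow(per))
}

#' Correlation between evoked responses and contact durations
#'
#' Spearman rank correlation (average-rank tie handling, two-sided p from the
#' t approximation) between per-event evoked responses and the durations of
#' the same contacts, as used to relate evoked activity to subsequent
#' investigation.
#'
#' @param dz per-event evoked responses, or an
#'   \linkS4class{EvokedResponseSet} (durations then taken from it).
#' @param durations per-event contact durations in seconds.
#' @param label when \code{dz} is an EvokedResponseSet: restrict to this
#'   stimulus label (default "mouse"); NULL keeps all events.
#' @return list with \code{rho}, \code{p}, \code{n}, \code{undefined} (TRUE
#'   when either vector is constant, in which case rho is NA).
#' @export
evokedDurationCorrelation <- function(dz, durations = NULL, label = "mouse") {
    if (is(dz, "EvokedResponseSet")) {
        r <- events(dz)
        if (!is.null(label)) r <- r[r$label == label, , drop = FALSE]
        durations <- r$duration
        dz <- r$dz
    }
    stopIfNot(length(dz) == length(durations),
              "dz and durations must have equal length")
    stopIfNot(length(dz) >= 3L, "need >= 3 paired observations, got %d",
              length(dz))
    if (stats::sd(dz) == 0 || stats::sd(durations) == 0)
        return(list(rho = NA_real_, p = NA_real_, n = length(dz),
                    undefined = TRUE))
    ct <- suppressWarnings(stats::cor.test(dz, durations,
                                           method = "spearman",
                                           exact = FALSE))
    list(rho = as.numeric(ct$estimate), p = ct$p.value, n = length(dz),
         undefined = FALSE)
}
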