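# Seeded generator for fiber-photometry sessions: slow drift + white noise +
# contact-locked calcium transients with known ground truth.

#' Configuration for the photometry session generator
#'
#' A session consists of a home-cage baseline segment of
#' \code{baselineMinutes} followed by \code{sessionSeconds} of behaviour,
#' sampled at \code{rate}. The raw trace is
#' \code{offset + drift + noise + sum of planted transients}; the baseline
#' segment never contains transients. Transient amplitudes are specified in z
#' units (multiples of the noise SD), so downstream z-scoring recovers them
#' directly; when \code{noiseSd = 0} amplitudes are in raw units.
#'
#' Defaults emulate the recording conditions the analyses are designed for:
#' 100 Hz sampling, a 5 min home-cage baseline, a 10 min test session, a
#' fluorescence level of 100 a.u. with 0.5\% white noise, and a cubic drift
#' spanning 10\% of the signal level.
#'
#' @param rate sampling rate, samples/s.
#' @param baselineMinutes duration of the pre-session home-cage segment (min).
#' @param sessionSeconds duration of the behavioural segment (s).
#' @param offset mean fluorescence level (a.u.).
#' @param driftAmplitude peak-to-peak amplitude of the slow drift (a.u.).
#' @param driftDegree polynomial degree of the drift (coefficients drawn from
#'   the seed, curve rescaled to \code{driftAmplitude}).
#' @param noiseSd white-noise SD (a.u.).
#' @param transientAmplitude named vector of planted evoked sizes (z units)
#'   per stimulus label.
#' @param kernelRise,kernelDecay difference-of-exponentials time constants (s)
#'   of the calcium-indicator-like transient.
#' @param shape \code{"dexp"} (difference of exponentials, peak-normalized) or
#'   \code{"step"} (rectangular step of \code{stepDuration} s).
#' @param stepDuration step length in s when \code{shape = "step"}.
#' @param events optional data.frame (onset, offset, label) in absolute
#'   seconds; must lie inside the behavioural segment, onsets strictly
#'   increasing. When NULL a regular alternating schedule is generated.
#' @param nEventsPerLabel events per label for the automatic schedule.
#' @param eventDuration bout length(s) in s for the automatic schedule;
#'   recycled over events, so a vector plants varying contact durations.
#' @param eventGap gap between an offset and the next onset (s) in the
#'   automatic schedule (>= 10 keeps every event nonsequential).
#' @param seed integer seed.
#' @return validated list of class \code{photoSimConfig}.
#' @export
photoSimConfig <- function(rate = 100, baselineMinutes = 5,
                           sessionSeconds = 600, offset = 100,
                           driftAmplitude = 10, driftDegree = 3L,
                           noiseSd = 0.5,
                           transientAmplitude = c(mouse = 2, object = 0.5),
                           kernelRise = 0.2, kernelDecay = 1.0,
                           shape = c("dexp", "step"), stepDuration = 3,
                           events = NULL, nEventsPerLabel = 10L,
                           eventDuration = c(1.5, 2.5, 2, 3), eventGap = 12,
                           seed = 1L) {
    shape <- match.arg(shape)
    stopIfNot(rate > 0, "rate must be > 0")
    stopIfNot(baselineMinutes > 0 && sessionSeconds > 0,
              "segment durations must be positive")
    stopIfNot(noiseSd >= 0, "noiseSd must be >= 0")
    stopIfNot(kernelRise > 0 && kernelDecay > kernelRise,
              "need 0 < kernelRise < kernelDecay")
    stopIfNot(!is.null(names(transientAmplitude)),
              "transientAmplitude must be a named vector")
    base_end <- baselineMinutes * 60
    total <- base_end + sessionSeconds
    if (is.null(events)) {
        labels <- rep(names(transientAmplitude), times = nEventsPerLabel)
        labels <- labels[order(rep(seq_len(nEventsPerLabel),
                                   each = length(transientAmplitude)))]
        n <- length(labels)
        dur <- rep_len(eventDuration, n)
        onsets <- base_end + 10 + cumsum(c(0, dur[-n] + eventGap))
        events <- data.frame(onset = onsets,
                             offset = onsets + dur,
                             label = labels)
    }
    events <- as.data.frame(events)
    stopIfNot(all(c("onset", "offset", "label") %in% colnames(events)),
              "events must have columns onset, offset, label")
    stopIfNot(!nrow(events) || all(events$onset >= base_end),
              "events overlap the baseline segment")
    stopIfNot(!nrow(events) || max(events$offset) <= total,
              "events fall outside the session segment")
    stopIfNot(!is.unsorted(events$onset, strictly = TRUE),
              "event onsets must be strictly increasing")
    structure(list(rate = rate, baselineMinutes = baselineMinutes,
                   sessionSeconds = sessionSeconds, offset = offset,
                   driftAmplitude = driftAmplitude,
                   driftDegree = as.integer(driftDegree), noiseSd = noiseSd,
                   transientAmplitude = transientAmplitude,
                   kernelRise = kernelRise, kernelDecay = kernelDecay,
                   shape = shape, stepDuration = stepDuration,
                   events = events, seed = as.integer(seed)),
              class = "photoSimConfig")
}

#' Mean of the transient kernel over the post-contact window
#'
#' For the peak-normalized difference-of-exponentials kernel
#' \code{h(t) = (exp(-t/decay) - exp(-t/rise)) / hmax}, returns the average of
#' \code{h} over \code{[0, window)} in closed form; for the step shape,
#' \code{min(stepDuration, window) / window}. Multiplied by the planted
#' amplitude this is the expected evoked response of a single transient.
#'
#' @param rise,decay time constants in s.
#' @param window window width in s (3 s by default).
#' @param shape "dexp" or "step".
#' @param stepDuration step length in s for the step shape.
#' @export
kernelWindowMean <- function(rise = 0.2, decay = 1.0, window = 3,
                             shape = c("dexp", "step"), stepDuration = 3) {
    shape <- match.arg(shape)
    if (shape == "step") return(min(stepDuration, window) / window)
    tpk <- log(decay / rise) * rise * decay / (decay - rise)
    hmax <- exp(-tpk / decay) - exp(-tpk / rise)
    (decay * (1 - exp(-window / decay)) - rise * (1 - exp(-window / rise))) /
        (window * hmax)
}

# kernel samples on the trace grid, peak-normalized (dexp) or unit step
transientKernel <- function(config) {
    dt <- 1 / config$rate
    if (config$shape == "step")
        return(rep(1, max(1L, round(config$stepDuration / dt))))
    tt <- seq(0, config$kernelDecay * 8, by = dt)
    tpk <- log(config$kernelDecay / config$kernelRise) * config$kernelRise *
        config$kernelDecay / (config$kernelDecay - config$kernelRise)
    hmax <- exp(-tpk / config$kernelDecay) - exp(-tpk / config$kernelRise)
    (exp(-tt / config$kernelDecay) - exp(-tt / config$kernelRise)) / hmax
}

#' Simulate a fiber-photometry session
#'
#' Generates a raw \linkS4class{PhotometryTrace} (drift + noise + transients),
#' the matching \linkS4class{EventLog}, and the ground truth of every planted
#' quantity. Identical configs give identical sessions.
#'
#' @param config a \code{\link{photoSimConfig}}.
#' @return list with elements \code{trace}, \code{events} and \code{truth}
#'   (list: drift curve incl. offset, noiseSd, per-event amplitudes in z and
#'   raw units, kernel window mean, event table).
#' @examples
#' ses <- simPhotometrySession(photoSimConfig(baselineMinutes = 0.5,
#'                                            sessionSeconds = 120,
#'                                            nEventsPerLabel = 3))
#' @export
simPhotometrySession <- function(config) {
    stopIfNot(inherits(config, "photoSimConfig"),
              "config must come from photoSimConfig()")
    dt <- 1 / config$rate
    total <- config$baselineMinutes * 60 + config$sessionSeconds
    n <- round(total * config$rate)
    tm <- (seq_len(n) - 1L) * dt
    ev <- config$events
    ampZ <- config$transientAmplitude[as.character(ev$label)]
    stopIfNot(!anyNA(ampZ), "event label without a configured amplitude")
    # planted amplitude in raw fluorescence units; z units are multiples of
    # the noise SD, which is what baseline z-scoring divides by
    ampRaw <- as.numeric(ampZ) * if (config$noiseSd > 0) config$noiseSd else 1
    out <- withSeed(config$seed, {
        drift <- rep(0, n)
        if (config$driftDegree >= 1L && config$driftAmplitude > 0) {
            u <- tm / total
            co <- stats::runif(config$driftDegree, -1, 1)
            raw <- colSums(t(outer(u, seq_len(config$driftDegree), `^`)) * co)
            rng <- diff(range(raw))
            if (rng > 0) drift <- (raw - mean(raw)) / rng * config$driftAmplitude
        }
        noise <- if (config$noiseSd > 0) stats::rnorm(n, 0, config$noiseSd)
                 else rep(0, n)
        list(drift = drift, noise = noise)
    })
    kern <- transientKernel(config)
    trans <- rep(0, n)
    for (i in seq_len(nrow(ev))) {
        i0 <- round(ev$onset[i] / dt) + 1L
        idx <- i0:min(n, i0 + length(kern) - 1L)
        trans[idx] <- trans[idx] + ampRaw[i] * kern[seq_along(idx)]
    }
    signal <- config$offset + out$drift + out$noise + trans
    trace <- PhotometryTrace(tm, signal, config$rate,
                             c(0, config$baselineMinutes * 60))
    truth <- list(drift = config$offset + out$drift,
                  noiseSd = config$noiseSd,
                  transientFree = trans == 0,
                  eventAmplitudeZ = stats::setNames(as.numeric(ampZ),
                                                    as.character(ev$label)),
                  eventAmplitudeRaw = ampRaw,
                  kernelWindowMean = kernelWindowMean(
                      config$kernelRise, config$kernelDecay, 3,
                      config$shape, config$stepDuration),
                  events = ev)
    list(trace = trace, events = EventLog(ev), truth = truth)
}
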