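# airPLS, z-scoring, event filtering, evoked responses, session statistics

test_that("airPLS reproduces penalty-null-space inputs exactly", {
    y <- rep(3.7, 200)
    fit <- airplsBaseline(y, lambda = 1e4, order = 2)
    expect_lt(max(abs(baseline(fit) - 3.7)), 1e-8)
    line <- 2 + 0.05 * seq_len(500)
    fitL <- airplsBaseline(line, lambda = 1e4, order = 2)
    expect_lt(max(abs(baseline(fitL) - line)), 1e-6)
})

test_that("airPLS recovers a cubic drift under positive transients", {
    cfg <- photoSimConfig(baselineMinutes = 1, sessionSeconds = 300,
                          transientAmplitude = c(ev = 4),
                          nEventsPerLabel = 10, eventGap = 20, seed = 8)
    ses <- simPhotometrySession(cfg)
    fit <- airplsBaseline(ses$trace@signal, lambda = 1e10)
    free <- ses$truth$transientFree
    rmse <- sqrt(mean((baseline(fit)[free] - ses$truth$drift[free])^2))
    expect_lt(rmse / diff(range(ses$truth$drift)), 0.05)
})

test_that("stiffer penalties never roughen the airPLS baseline", {
    cfg <- photoSimConfig(baselineMinutes = 0.5, sessionSeconds = 60,
                          transientAmplitude = c(ev = 3),
                          nEventsPerLabel = 3, seed = 12)
    y <- simPhotometrySession(cfg)$trace@signal
    rough <- vapply(c(1e2, 1e4, 1e6, 1e8, 1e10), function(l)
        sum(diff(baseline(airplsBaseline(y, lambda = l)), differences = 2)^2),
        0)
    expect_true(all(diff(rough) <= 1e-12))
})

test_that("airPLS input validation", {
    expect_error(airplsBaseline(c(1, NA, rep(1, 10))), "finite")
    expect_error(airplsBaseline(rep(1, 100), lambda = 0), "lambda")
    expect_error(airplsBaseline(1:5), "length")
})

test_that("baseline-period z-scoring is exact, also after smoothing", {
    for (sw in c(0, 0.5)) {
        cfg <- photoSimConfig(baselineMinutes = 0.5, sessionSeconds = 60,
                              nEventsPerLabel = 2, seed = 14 + sw)
        ses <- simPhotometrySession(cfg)
        fit <- airplsBaseline(ses$trace@signal, lambda = 1e10)
        zt <- correctAndZscore(ses$trace, fit, smoothWindow = sw)
        idx <- zt@time >= 0 & zt@time < 30
        expect_lt(abs(mean(zt@z[idx])), 1e-8)
        expect_lt(abs(stats::sd(zt@z[idx]) - 1), 1e-8)
    }
})

test_that("unit z-score definition and degenerate baseline segment", {
    # craft a trace: known baseline moments, one session sample 1 SD above
    base <- rep(c(9, 11), 250)           # mean 10, SD just above 1
    sdv <- stats::sd(base)
    tr <- PhotometryTrace(time = (0:(length(base) + 9) ) / 100,
                          signal = c(base, rep(10 + sdv, 10)),
                          rate = 100, baselineWindow = c(0, 5))
    zt <- correctAndZscore(tr)
    expect_equal(zt@z[length(base) + 1L], 1, tolerance = 1e-12)
    flat <- PhotometryTrace(time = (0:99) / 100, signal = rep(5, 100),
                            rate = 100, baselineWindow = c(0, 0.5))
    expect_error(correctAndZscore(flat), "zero SD")
})

test_that("white-noise sessions have near-zero session mean z", {
    cfg <- photoSimConfig(baselineMinutes = 2, sessionSeconds = 120,
                          driftAmplitude = 0, noiseSd = 1,
                          transientAmplitude = c(mouse = 0, object = 0),
                          nEventsPerLabel = 2, seed = 33)
    ses <- simPhotometrySession(cfg)
    zt <- correctAndZscore(ses$trace)
    n <- length(zt@z)
    expect_lt(abs(mean(zt@z)), 4 / sqrt(n))
})

test_that("nonsequential filter follows the full-log gap rule", {
    log <- EventLog(data.frame(onset = c(0, 12, 30), offset = c(5, 14, 31),
                               label = "mouse"))
    kept <- events(selectNonsequentialEvents(log, 10))
    expect_equal(kept$onset, c(0, 30))
    # single event is kept; an exact 10 s gap is kept (inclusive boundary)
    expect_identical(nrow(events(selectNonsequentialEvents(
        EventLog(data.frame(onset = 1, offset = 2, label = "m"))))), 1L)
    bnd <- EventLog(data.frame(onset = c(0, 15, 30), offset = c(5, 20, 35),
                               label = "m"))
    expect_identical(nrow(events(selectNonsequentialEvents(bnd, 10))), 3L)
    # overlapping logs are rejected at construction
    expect_error(EventLog(data.frame(onset = c(0, 3), offset = c(5, 7),
                                     label = "m")), "overlap")
})

test_that("filter matches exhaustive rule application and is idempotent", {
    withr::with_seed(71, {
        for (r in 1:50) {
            ev <- randomEventLog(sample(1:30, 1))
            log <- EventLog(ev)
            f1 <- selectNonsequentialEvents(log, 10)
            ref <- bruteNonseqFilter(events(log), 10)
            expect_equal(events(f1)$onset, ref$onset)
            f2 <- selectNonsequentialEvents(f1, 10)
            expect_identical(events(f1), events(f2))
        }
    })
})

test_that("evoked response recovers steps exactly and is shift-invariant", {
    # z steps from 0 to a at t = 10 s into the session
    sess <- c(rep(0, 1000), rep(2.5, 1000))
    zt <- makeZTrace(sess, nBaseline = 500)
    onset <- (500 + 1000) / 100
    expect_equal(evokedResponse(zt, onset), 2.5, tolerance = 1e-12)
    # constant signal -> zero
    ztc <- makeZTrace(rep(4, 2000))
    expect_equal(evokedResponse(ztc, 10), 0)
    # adding a constant to the whole session leaves dz unchanged
    zt2 <- makeZTrace(sess + 1.23, nBaseline = 500)
    expect_equal(evokedResponse(zt2, onset), evokedResponse(zt, onset),
                 tolerance = 1e-12)
    # truncated windows are skipped with a warning and counted
    lg <- EventLog(data.frame(onset = c(1, 12), offset = c(2, 13),
                              label = "m"))
    expect_warning(rs <- evokedResponses(makeZTrace(rep(0, 1200)), lg),
                   "skipped")
    expect_identical(rs@skipped, 1L)
})

test_that("planted transients are recovered without bias", {
    # drift-free session; mean dz over events within Monte-Carlo bounds of
    # amplitude x kernel window mean
    a <- 2; sigma <- 1; nev <- 40
    cfg <- photoSimConfig(baselineMinutes = 2,
                          sessionSeconds = nev * 14 + 20, noiseSd = sigma,
                          driftAmplitude = 0,
                          transientAmplitude = c(mouse = a),
                          nEventsPerLabel = nev, eventDuration = 2,
                          eventGap = 12, seed = 91)
    ses <- simPhotometrySession(cfg)
    zt <- correctAndZscore(ses$trace)
    rs <- evokedResponses(zt, selectNonsequentialEvents(ses$events))
    dz <- events(rs)$dz
    expect_identical(length(dz), as.integer(nev))
    target <- a * ses$truth$kernelWindowMean
    se <- sigma * sqrt(2 / 300) / sqrt(nev)
    expect_lt(abs(mean(dz) - target), 4 * se)
})

test_that("session summary handles exact and degenerate paired contrasts", {
    df <- data.frame(animal = rep(paste0("a", 1:4), each = 2),
                     label = rep(c("mouse", "object"), 4),
                     dz = rep(c(0.4, 0.4), 4))
    s <- sessionEvokedSummary(df)
    expect_equal(s$t, 0); expect_equal(s$p, 1)
    dfc <- df; dfc$dz <- rep(c(1.4, 0.4), 4)   # constant nonzero differences
    sc <- sessionEvokedSummary(dfc)
    expect_true(sc$degenerate)
    expect_true(is.na(sc$t))
    dfm <- df[-2, ]                            # a1 lacks the object label
    expect_error(sessionEvokedSummary(dfm), "a1")
    # ordinary case agrees with stats::t.test on the paired differences
    withr::with_seed(13, {
        dfr <- data.frame(animal = rep(paste0("a", 1:7), each = 2),
                          label = rep(c("mouse", "object"), 7),
                          dz = rnorm(14, rep(c(0.8, 0.2), 7), 0.3))
        sr <- sessionEvokedSummary(dfr)
        d <- dfr$dz[dfr$label == "mouse"] - dfr$dz[dfr$label == "object"]
        tt <- t.test(d)
        expect_equal(sr$t, unname(tt$statistic))
        expect_equal(sr$p, tt$p.value)
    })
})

test_that("response-duration correlation uses average ranks", {
    expect_equal(evokedDurationCorrelation(1:5, c(2, 3, 5, 7, 11))$rho, 1)
    expect_equal(evokedDurationCorrelation(1:5, rev(c(2, 3, 5, 7, 11)))$rho, -1)
    a <- c(1, 2, 2, 3, 5, 5, 5)
    b <- c(2, 1, 4, 4, 6, 8, 8)
    expect_equal(evokedDurationCorrelation(a, b)$rho, bruteSpearman(a, b),
                 tolerance = 1e-12)
    expect_true(evokedDurationCorrelation(rep(1, 5), 1:5)$undefined)
    expect_error(evokedDurationCorrelation(1:2, 1:2), ">= 3")
})

test_that("a planted social preference yields a significant paired contrast", {
    # scaled-down end-to-end cohort: 7 animals, airPLS included
    sig <- 0
    for (r in 1:5) {
        perA <- data.frame()
        for (a in 1:7) {
            cfg <- photoSimConfig(baselineMinutes = 0.5, sessionSeconds = 125,
                                  transientAmplitude = c(mouse = 2,
                                                         object = 0.5),
                                  nEventsPerLabel = 4, eventGap = 12,
                                  seed = 5000 + r * 20 + a)
            ses <- simPhotometrySession(cfg)
            fit <- airplsBaseline(ses$trace@signal, lambda = 1e10)
            zt <- correctAndZscore(ses$trace, fit)
            rs <- evokedResponses(zt, selectNonsequentialEvents(ses$events))
            ev <- events(rs)
            perA <- rbind(perA, data.frame(animal = paste0("a", a),
                                           label = ev$label, dz = ev$dz))
        }
        s <- sessionEvokedSummary(perA)
        sig <- sig + (s$p < 0.05)
    }
    expect_gte(sig, 4)
})
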