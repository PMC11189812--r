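#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

# ---------------------------------------------------------------------------
# Region-level cell counts
# ---------------------------------------------------------------------------

#' Brain-wide IEG cell-count table
#'
#' Container for per-animal, per-region counts of IEG-reporter-positive cells
#' (e.g. Arc-driven dVenus), stored as a \linkS4class{SummarizedExperiment}
#' with regions as rows and animals as columns. The treatment group of each
#' animal lives in \code{colData(x)$group}.
#'
#' @slot .Data see \linkS4class{SummarizedExperiment}; assay \code{"counts"}
#'   holds nonnegative integer cell counts.
#' @export
setClass("CellCountTable", contains = "SummarizedExperiment")

setValidity("CellCountTable", function(object) {
    m <- SummarizedExperiment::assay(object, "counts")
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
        return("region names must be present and unique")
    if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
        return("animal ids must be present and unique")
    if (any(!is.finite(m)))
        return("counts must be finite")
    if (any(m < 0))
        return("counts must be nonnegative")
    if (max(abs(m - round(m))) > 1e-8)
        return("counts must be integers")
    cd <- SummarizedExperiment::colData(object)
    if (!"group" %in% colnames(cd))
        return("colData must contain a 'group' column")
    if (!is.factor(cd$group))
        return("'group' must be a factor (the declared label set)")
    TRUE
})

#' Construct a CellCountTable
#'
#' @param counts numeric matrix of nonnegative integer cell counts, regions in
#'   rows and animals in columns (Bioconductor convention).
#' @param group treatment label per animal (character or factor, length
#'   \code{ncol(counts)}).
#' @param groupLevels declared set of group labels; defaults to the labels
#'   present, in order of first appearance.
#' @return A \linkS4class{CellCountTable}.
#' @examples
#' m <- matrix(rpois(44, 100), nrow = 22,
#'             dimnames = list(defaultRegionNames(22), paste0("a", 1:2)))
#' CellCountTable(m, group = c("saline", "R-ket"))
#' @export
CellCountTable <- function(counts, group,
                           groupLevels = unique(as.character(group))) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    group <- factor(as.character(group), levels = groupLevels)
    stopIfNot(length(group) == ncol(counts),
              "need one group label per animal (%d animals, %d labels)",
              ncol(counts), length(group))
    stopIfNot(!anyNA(group), "group labels outside the declared level set")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(group = group,
                                       row.names = colnames(counts)))
    new("CellCountTable", se)
}

# ---------------------------------------------------------------------------
# z-scored counts
# ---------------------------------------------------------------------------

#' Region-wise z-score matrix
#'
#' Animals x regions matrix of z-scored cell counts together with the
#' per-region standardization constants (mean and sample SD, in cells) and the
#' group label of every animal in the standardization cohort.
#'
#' @slot z numeric matrix, animals x regions, dimensionless.
#' @slot centers,scales per-region mean and sample SD (denominator n - 1).
#' @slot groups factor of treatment labels, one per animal (row).
#' @export
setClass("ZScoreMatrix",
         representation(z = "matrix", centers = "numeric", scales = "numeric",
                        groups = "factor"))

setValidity("ZScoreMatrix", function(object) {
    z <- object@z
    if (length(object@centers) != ncol(z) || length(object@scales) != ncol(z))
        return("one center and scale per region required")
    if (length(object@groups) != nrow(z))
        return("one group label per animal required")
    cm <- colMeans(z)
    csd <- apply(z, 2L, stats::sd)
    if (max(abs(cm)) > 1e-10 || max(abs(csd - 1)) > 1e-10)
        return("columns must have mean 0 and sample SD 1 within 1e-10")
    TRUE
})

# ---------------------------------------------------------------------------
# Classifier and forward-model pattern
# ---------------------------------------------------------------------------

#' Linear SVM classifier model
#'
#' Soft-margin linear support vector machine fitted on a two-group subset of a
#' \linkS4class{ZScoreMatrix}. Predictions on the training data are fully
#' reproducible from \code{weights} and \code{intercept}.
#'
#' @slot weights region-indexed weight vector W (backward model).
#' @slot intercept scalar bias b.
#' @slot positive,negative class labels mapped to +1 / -1.
#' @slot cost soft-margin regularization constant C.
#' @slot alpha dual coefficients (one per training animal).
#' @slot rowIndex rows of the standardization cohort used for the fit.
#' @slot trainAccuracy,margin training diagnostics (fraction correct; 2/|W|).
#' @slot dualObjective value of the dual objective 0.5 a'Qa - sum(a) at the
#'   solution (a minimization; more negative is better).
#' @slot iterations,converged solver diagnostics.
#' @export
setClass("ClassifierModel",
         representation(weights = "numeric", intercept = "numeric",
                        positive = "character", negative = "character",
                        cost = "numeric", alpha = "numeric",
                        rowIndex = "integer", trainAccuracy = "numeric",
                        margin = "numeric", dualObjective = "numeric",
                        iterations = "integer", converged = "logical"))

setValidity("ClassifierModel", function(object) {
    if (!all(is.finite(object@weights))) return("non-finite weights")
    if (sum(abs(object@weights)) == 0) return("degenerate fit: |W| = 0")
    TRUE
})

#' Forward-model activation pattern
#'
#' The activation pattern A = Sigma_x W Sigma_s^-1 obtained from a linear
#' classifier's weight vector W and the covariance Sigma_x of the data it was
#' fitted on, with Sigma_s = W' Sigma_x W the (scalar, K = 1) covariance of
#' the latent decision variable. A is interpretable region by region as each
#' area's contribution to the discriminated signal, unlike W itself.
#'
#' @slot A region-indexed activation pattern.
#' @slot sigmaX data covariance matrix (M x M, unbiased, pooled grand-mean
#'   centering over the two-group comparison data).
#' @slot sigmaS scalar latent-factor variance W' Sigma_x W.
#' @slot weights the backward-model weights the pattern was derived from.
#' @slot positive,negative the class labels of the underlying comparison.
#' @export
setClass("ActivationPattern",
         representation(A = "numeric", sigmaX = "matrix", sigmaS = "numeric",
                        weights = "numeric", positive = "character",
                        negative = "character"))

setValidity("ActivationPattern", function(object) {
    if (object@sigmaS <= 0) return("sigmaS must be positive")
    if (max(abs(object@sigmaX - t(object@sigmaX))) > 1e-10)
        return("sigmaX must be symmetric")
    resid <- object@sigmaX %*% object@weights / object@sigmaS - object@A
    if (max(abs(resid)) > 1e-10)
        return("A = sigmaX W sigmaS^-1 violated beyond 1e-10")
    TRUE
})

# ---------------------------------------------------------------------------
# Insular-cortex cell coordinates and AP distribution
# ---------------------------------------------------------------------------

#' Per-cell stereotaxic coordinates
#'
#' 3-D coordinates (mm relative to bregma) of labelled cells, typically in the
#' insular cortex, with animal and treatment annotation. Columns:
#' \code{animal_id}, \code{group}, \code{ap_mm}, \code{ml_mm}, \code{dv_mm}.
#'
#' @slot cells data.frame of per-cell records.
#' @export
setClass("CellCoordinateSet", representation(cells = "data.frame"))

setValidity("CellCoordinateSet", function(object) {
    need <- c("animal_id", "group", "ap_mm", "ml_mm", "dv_mm")
    if (!all(need %in% colnames(object@cells)))
        return(paste("cells must have columns", paste(need, collapse = ", ")))
    if (nrow(object@cells) && any(!is.finite(object@cells$ap_mm)))
        return("non-finite AP coordinate")
    TRUE
})

#' @rdname CellCoordinateSet-class
#' @param cells data.frame with columns animal_id, group, ap_mm, ml_mm, dv_mm.
#' @export
CellCoordinateSet <- function(cells) new("CellCoordinateSet", cells = cells)

#' Anteroposterior cell-count distribution
#'
#' Histogram of labelled cells along the anteroposterior axis, per treatment,
#' over decreasing bin edges (anterior first). Bin i covers
#' (edges[i+1], edges[i]] (most posterior bin closed on both sides); cells
#' outside the edge span are counted in \code{overflow}, never dropped.
#'
#' @slot edges decreasing bin edges in mm relative to bregma.
#' @slot counts bins x treatments count matrix.
#' @slot overflow out-of-range cell count per treatment.
#' @slot subdivision aIC/mIC/pIC label per bin (midpoint rule; aIC is
#'   +2.50 to +1.45 mm).
#' @export
setClass("APDistribution",
         representation(edges = "numeric", counts = "matrix",
                        overflow = "numeric", subdivision = "character"))

setValidity("APDistribution", function(object) {
    if (any(diff(object@edges) >= 0)) return("edges must be decreasing")
    if (nrow(object@counts) != length(object@edges) - 1L)
        return("one count row per bin required")
    if (length(object@subdivision) != nrow(object@counts))
        return("one subdivision label per bin required")
    TRUE
})

# ---------------------------------------------------------------------------
# Photometry
# ---------------------------------------------------------------------------

#' Uniformly sampled fluorescence trace
#'
#' Raw single-wavelength fiber-photometry recording with a designated
#' home-cage baseline segment used later for z-scoring.
#'
#' @slot time time stamps in seconds (uniform grid).
#' @slot signal raw fluorescence (arbitrary units).
#' @slot rate sampling rate in samples/s.
#' @slot baselineWindow c(start, end) seconds of the baseline segment
#'   (half-open, end excluded).
#' @export
setClass("PhotometryTrace",
         representation(time = "numeric", signal = "numeric", rate = "numeric",
                        baselineWindow = "numeric"))

setValidity("PhotometryTrace", function(object) {
    if (length(object@time) != length(object@signal))
        return("time and signal lengths differ")
    if (anyNA(object@signal) || any(!is.finite(object@signal)))
        return("signal contains non-finite values")
    if (length(object@time) > 1L) {
        dt <- diff(object@time)
        if (max(abs(dt - 1 / object@rate)) > 1e-6 / object@rate)
            return("sampling is not uniform at the declared rate")
    }
    bw <- object@baselineWindow
    if (length(bw) != 2L || bw[2] <= bw[1])
        return("baselineWindow must be c(start, end) with end > start")
    if (bw[1] < object@time[1] - 1e-9 ||
        bw[2] > object@time[length(object@time)] + 1 / object@rate + 1e-9)
        return("baseline segment must lie within the recording")
    TRUE
})

#' @rdname PhotometryTrace-class
#' @param time,signal,rate,baselineWindow see slots.
#' @export
PhotometryTrace <- function(time, signal, rate, baselineWindow)
    new("PhotometryTrace", time = as.numeric(time), signal = as.numeric(signal),
        rate = rate, baselineWindow = as.numeric(baselineWindow))

#' airPLS baseline fit
#'
#' @slot baseline fitted slow baseline, same length as the input signal.
#' @slot lambda smoothness penalty.
#' @slot order difference order of the penalty.
#' @slot ratio termination ratio.
#' @slot iterations,converged solver diagnostics.
#' @export
setClass("BaselineFit",
         representation(baseline = "numeric", lambda = "numeric",
                        order = "integer", ratio = "numeric",
                        iterations = "integer", converged = "logical"))

#' Baseline-corrected, z-scored trace
#'
#' @slot time,rate as in \linkS4class{PhotometryTrace}.
#' @slot z baseline-corrected, optionally smoothed, z-scored signal; over the
#'   baseline segment it has mean 0 and SD 1 by construction.
#' @slot baselineWindow the segment used for standardization.
#' @slot baselineMean,baselineSD standardization constants (fluorescence units).
#' @slot smoothWindow moving-average width in seconds (0 = none).
#' @export
setClass("ZTrace",
         representation(time = "numeric", z = "numeric", rate = "numeric",
                        baselineWindow = "numeric", baselineMean = "numeric",
                        baselineSD = "numeric", smoothWindow = "numeric"))

setValidity("ZTrace", function(object) {
    if (length(object@time) != length(object@z))
        return("time and z lengths differ")
    idx <- object@time >= object@baselineWindow[1] &
        object@time < object@baselineWindow[2]
    if (sum(idx) >= 2L) {
        if (abs(mean(object@z[idx])) > 1e-8)
            return("baseline-segment z mean exceeds 1e-8")
        if (abs(stats::sd(object@z[idx]) - 1) > 1e-8)
            return("baseline-segment z SD differs from 1 beyond 1e-8")
    }
    TRUE
})

# ---------------------------------------------------------------------------
# Events and evoked responses
# ---------------------------------------------------------------------------

#' Investigation event log
#'
#' Onset-ordered, non-overlapping investigation bouts with stimulus labels
#' (e.g. mouse / object / cage-mate). Columns: \code{onset}, \code{offset}
#' (seconds), \code{label}, \code{trial}.
#'
#' @slot events data.frame of events.
#' @export
setClass("EventLog", representation(events = "data.frame"))

setValidity("EventLog", function(object) {
    ev <- object@events
    need <- c("onset", "offset", "label")
    if (!all(need %in% colnames(ev)))
        return(paste("events must have columns", paste(need, collapse = ", ")))
    if (nrow(ev)) {
        if (any(ev$offset <= ev$onset))
            return("every offset must exceed its onset")
        if (is.unsorted(ev$onset, strictly = TRUE))
            return("onsets must be strictly increasing")
        if (nrow(ev) > 1L && any(ev$onset[-1L] < ev$offset[-nrow(ev)]))
            return("events overlap")
    }
    TRUE
})

#' @rdname EventLog-class
#' @param events data.frame with columns onset, offset, label and optionally
#'   trial (filled in sequentially when absent).
#' @export
EventLog <- function(events) {
    events <- as.data.frame(events)
    if (nrow(events) && !"trial" %in% colnames(events))
        events$trial <- seq_len(nrow(events))
    if (!nrow(events))
        events <- data.frame(onset = numeric(0), offset = numeric(0),
                             label = character(0), trial = integer(0))
    new("EventLog", events = events[, c("onset", "offset", "label", "trial")])
}

#' Per-event evoked responses
#'
#' One row per analysable event with its evoked response
#' dz = mean z over [onset, onset + w) minus mean z over [onset - w, onset),
#' w = 3 s by default. Events whose windows would be truncated by the
#' recording edge are skipped and counted in \code{skipped}.
#'
#' @slot responses data.frame with columns label, onset, offset, duration, dz.
#' @slot skipped number of events dropped for truncated windows.
#' @slot window half-window width in seconds.
#' @export
setClass("EvokedResponseSet",
         representation(responses = "data.frame", skipped = "integer",
                        window = "numeric"))

setValidity("EvokedResponseSet", function(object) {
    if (nrow(object@responses) && any(!is.finite(object@responses$dz)))
        return("dz must be finite")
    TRUE
})
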