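# accessors and show methods

#' @describeIn CellCountTable-class cell-count matrix (regions x animals)
#' @param object a CellCountTable.
#' @export
setMethod("counts", "CellCountTable", function(object)
    SummarizedExperiment::assay(object, "counts"))

#' @describeIn CellCountTable-class region abbreviations
#' @param x a CellCountTable.
#' @export
setMethod("regionNames", "CellCountTable", function(x) rownames(x))

#' @describeIn CellCountTable-class treatment label per animal
#' @export
setMethod("groups", "CellCountTable", function(x)
    SummarizedExperiment::colData(x)$group)

#' @describeIn CellCountTable-class animal identifiers
#' @export
setMethod("animalIds", "CellCountTable", function(x) colnames(x))

setMethod("show", "CellCountTable", function(object) {
    cat(sprintf("CellCountTable: %d regions x %d animals\n",
                nrow(object), ncol(object)))
    print(table(groups(object)))
})

#' @describeIn ZScoreMatrix-class the z matrix (animals x regions)
#' @param x a ZScoreMatrix.
#' @export
setMethod("zscores", "ZScoreMatrix", function(x) x@z)

#' @describeIn ZScoreMatrix-class region abbreviations
#' @export
setMethod("regionNames", "ZScoreMatrix", function(x) colnames(x@z))

#' @describeIn ZScoreMatrix-class treatment label per animal
#' @export
setMethod("groups", "ZScoreMatrix", function(x) x@groups)

#' @describeIn ZScoreMatrix-class animal identifiers
#' @export
setMethod("animalIds", "ZScoreMatrix", function(x) rownames(x@z))

setMethod("show", "ZScoreMatrix", function(object) {
    cat(sprintf("ZScoreMatrix: %d animals x %d regions (per-region mean 0, SD 1)\n",
                nrow(object@z), ncol(object@z)))
})

#' @describeIn ClassifierModel-class region-indexed weight vector W
#' @param object a ClassifierModel.
#' @param ... ignored.
#' @importFrom stats weights
#' @export
setMethod("weights", "ClassifierModel", function(object, ...) object@weights)

setMethod("show", "ClassifierModel", function(object) {
    cat(sprintf("Linear SVM (%s [+1] vs %s [-1]), C = %g\n",
                object@positive, object@negative, object@cost))
    cat(sprintf("  %d features, training accuracy %.3f, margin %.4g\n",
                length(object@weights), object@trainAccuracy, object@margin))
    cat(sprintf("  dual objective %.8g (%s after %d updates)\n",
                object@dualObjective,
                if (object@converged) "converged" else "not converged",
                object@iterations))
})

#' @describeIn ActivationPattern-class the pattern vector A
#' @param x an ActivationPattern.
#' @export
setMethod("activation", "ActivationPattern", function(x) x@A)

#' @describeIn ActivationPattern-class region abbreviations
#' @export
setMethod("regionNames", "ActivationPattern", function(x) names(x@A))

setMethod("show", "ActivationPattern", function(object) {
    top <- names(object@A)[which.max(abs(object@A))]
    cat(sprintf("ActivationPattern (%s vs %s): M = %d regions, sigmaS = %.4g\n",
                object@positive, object@negative, length(object@A),
                object@sigmaS))
    cat(sprintf("  largest |A|: %s (%.4g)\n", top, max(abs(object@A))))
})

#' @describeIn CellCoordinateSet-class per-cell coordinate table
#' @param x a CellCoordinateSet.
#' @export
setGeneric("cellCoords", function(x) standardGeneric("cellCoords"))

#' @describeIn CellCoordinateSet-class per-cell coordinate table
#' @export
setMethod("cellCoords", "CellCoordinateSet", function(x) x@cells)

#' @describeIn CellCoordinateSet-class treatment label per cell
#' @export
setMethod("groups", "CellCoordinateSet", function(x) x@cells$group)

setMethod("show", "CellCoordinateSet", function(object) {
    cat(sprintf("CellCoordinateSet: %d cells, %d animals\n",
                nrow(object@cells), length(unique(object@cells$animal_id))))
    if (nrow(object@cells))
        cat(sprintf("  AP range: %+.2f to %+.2f mm\n",
                    max(object@cells$ap_mm), min(object@cells$ap_mm)))
})

#' @describeIn APDistribution-class per-bin, per-treatment counts
#' @param x an APDistribution.
#' @export
setGeneric("apCounts", function(x) standardGeneric("apCounts"))

#' @describeIn APDistribution-class per-bin, per-treatment counts
#' @export
setMethod("apCounts", "APDistribution", function(x) x@counts)

setMethod("show", "APDistribution", function(object) {
    cat(sprintf("APDistribution: %d bins, %+.2f to %+.2f mm\n",
                nrow(object@counts), object@edges[1],
                object@edges[length(object@edges)]))
    cat(sprintf("  overflow: %s\n",
                paste(sprintf("%s=%d", colnames(object@counts),
                              as.integer(object@overflow)), collapse = ", ")))
})

setMethod("show", "PhotometryTrace", function(object) {
    cat(sprintf("PhotometryTrace: %d samples at %g Hz (%.1f s), baseline [%g, %g) s\n",
                length(object@signal), object@rate,
                length(object@signal) / object@rate,
                object@baselineWindow[1], object@baselineWindow[2]))
})

#' @describeIn BaselineFit-class fitted slow baseline vector
#' @param x a BaselineFit.
#' @export
setMethod("baseline", "BaselineFit", function(x) x@baseline)

setMethod("show", "BaselineFit", function(object) {
    cat(sprintf("airPLS BaselineFit: lambda = %g, order %d, %d iterations (%s)\n",
                object@lambda, object@order, object@iterations,
                if (object@converged) "converged" else "hit max_iter"))
})

setMethod("show", "ZTrace", function(object) {
    cat(sprintf("ZTrace: %d samples at %g Hz; baseline mean %.4g, SD %.4g (a.u.)\n",
                length(object@z), object@rate, object@baselineMean,
                object@baselineSD))
})

#' @describeIn EventLog-class event table
#' @param x an EventLog.
#' @export
setMethod("events", "EventLog", function(x) x@events)

setMethod("length", "EventLog", function(x) nrow(x@events))

setMethod("show", "EventLog", function(object) {
    cat(sprintf("EventLog: %d events\n", nrow(object@events)))
    if (nrow(object@events)) print(table(object@events$label))
})

#' @describeIn EvokedResponseSet-class per-event response table
#' @param x an EvokedResponseSet.
#' @export
setMethod("events", "EvokedResponseSet", function(x) x@responses)

setMethod("show", "EvokedResponseSet", function(object) {
    cat(sprintf("EvokedResponseSet: %d events (+%d skipped), window +/- %g s\n",
                nrow(object@responses), object@skipped, object@window))
    if (nrow(object@responses)) {
        m <- tapply(object@responses$dz, object@responses$label, mean)
        cat("  mean dz by label:",
            paste(sprintf("%s=%.3f", names(m), m), collapse = ", "), "\n")
    }
})
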