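# Region-wise z-scoring of cell-count tables.

#' Standardize a cell-count table into z-scores
#'
#' Each region's counts are standardized across the whole cohort (all animals
#' of all groups jointly) to mean 0 and sample SD 1 (denominator n - 1).
#' Standardizing over the full three-group cohort, before any two-group
#' subsetting, preserves the cross-group scale when a pairwise classifier is
#' fitted later.
#'
#' @param table a \linkS4class{CellCountTable} with >= 2 animals.
#' @return a \linkS4class{ZScoreMatrix} (animals x regions) carrying the
#'   standardization constants.
#' @examples
#' sim <- simCellCounts(countSimConfig(seed = 1))
#' z <- standardizeCounts(sim$table)
#' colMeans(zscores(z))  # ~ 0
#' @export
standardizeCounts <- function(table) {
    stopIfNot(is(table, "CellCountTable"),
              "table must be a CellCountTable")
    m <- t(counts(table))            # animals x regions
    stopIfNot(nrow(m) >= 2L, "need at least 2 animals, got %d", nrow(m))
    ctr <- colMeans(m)
    sds <- apply(m, 2L, stats::sd)
    if (any(sds == 0))
        stop(sprintf("zero-variance region(s): %s",
                     paste(colnames(m)[sds == 0], collapse = ", ")),
             call. = FALSE)
    z <- sweep(sweep(m, 2L, ctr, `-`), 2L, sds, `/`)
    new("ZScoreMatrix", z = z, centers = ctr, scales = sds,
        groups = groups(table))
}
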