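# Seeded generator for insular-cortex cell coordinate clouds along the
# anteroposterior (AP) axis.

#' Simulate insular-cortex cell coordinates
#'
#' Places \code{nCells} cells along the AP axis inside \code{apRange}
#' (mm relative to bregma, anterior edge first) according to a density
#' profile, with mediolateral and dorsoventral coordinates drawn uniformly
#' from plausible insular-cortex spans (ML 2.2--4.2 mm, DV -4.5 to -2.0 mm).
#'
#' @param nCells number of cells (>= 0).
#' @param apRange c(anterior, posterior) mm; must lie within +2.50 to -1.00.
#' @param profile either \code{"uniform"} or a vector of nonnegative weights
#'   over equally wide sub-intervals of \code{apRange} (anterior first);
#'   within a sub-interval cells are uniform.
#' @param animalId,group annotation applied to every cell; vectors are
#'   recycled cell-wise so multi-animal clouds can be drawn in one call.
#' @param seed integer seed.
#' @return a \linkS4class{CellCoordinateSet}.
#' @examples
#' cc <- simICCoordinates(500, profile = c(3, 1, 1, 1), seed = 2)
#' @export
simICCoordinates <- function(nCells, apRange = c(2.50, -1.00),
                             profile = "uniform", animalId = "sim1",
                             group = "R-ket", seed = 1L) {
    stopIfNot(isCount(nCells), "nCells must be a nonnegative integer")
    stopIfNot(length(apRange) == 2L && apRange[1] > apRange[2],
              "apRange must be c(anterior, posterior) with anterior > posterior")
    stopIfNot(apRange[1] <= 2.50 + 1e-9 && apRange[2] >= -1.00 - 1e-9,
              "apRange must lie within +2.50 to -1.00 mm")
    if (identical(profile, "uniform")) profile <- 1
    profile <- as.numeric(profile)
    stopIfNot(all(profile >= 0) && sum(profile) > 0,
              "profile weights must be nonnegative and not all zero")
    nCells <- as.integer(nCells)
    k <- length(profile)
    sub <- seq(apRange[1], apRange[2], length.out = k + 1L)  # decreasing
    cells <- withSeed(seed, {
        bin <- sample.int(k, nCells, replace = TRUE, prob = profile / sum(profile))
        u <- stats::runif(nCells)
        ap <- sub[bin] + u * (sub[bin + 1L] - sub[bin])
        data.frame(animal_id = rep_len(animalId, nCells),
                   group = rep_len(group, nCells),
                   ap_mm = ap,
                   ml_mm = stats::runif(nCells, 2.2, 4.2),
                   dv_mm = stats::runif(nCells, -4.5, -2.0))
    })
    if (!nCells)
        cells <- data.frame(animal_id = character(0), group = character(0),
                            ap_mm = numeric(0), ml_mm = numeric(0),
                            dv_mm = numeric(0))
    CellCoordinateSet(cells)
}
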