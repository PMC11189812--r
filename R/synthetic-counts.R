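# Seeded generator for brain-wide IEG cell-count tables with plantable
# group effects.

#' Default brain-region abbreviation set
#'
#' Allen-atlas-style abbreviations for the 22 parcellated areas used by the
#' count analyses; for other sizes generic labels \code{R01..} are returned.
#'
#' @param n number of regions.
#' @return character vector of length \code{n}.
#' @export
defaultRegionNames <- function(n = 22L) {
    full <- c("ACC", "PL", "IL", "ORB", "MO", "SS", "GU", "VISC", "AUD",
              "VIS", "RSP", "PTLp", "TEa", "PERI", "ECT", "IC", "CLA",
              "STR", "TH", "HY", "HIP", "AMY")
    if (n == length(full)) full else sprintf("R%02d", seq_len(n))
}

#' Configuration for the cell-count generator
#'
#' Counts are drawn per animal and region from a negative binomial with
#' region-specific mean and a common dispersion (size) parameter, so the
#' across-animal overdispersion typical of biological count tables is
#' representable. A group effect is planted additively on the mean of the
#' designated group in the chosen regions, expressed in units of the
#' within-group SD \code{sqrt(mu + mu^2/dispersion)}.
#'
#' @param nPerGroup animals per group (>= 2).
#' @param groups ordered treatment labels.
#' @param nRegions number of brain regions.
#' @param regionNames region abbreviations; defaults to
#'   \code{defaultRegionNames(nRegions)}.
#' @param baselineMean expected count per region (cells, > 0); recycled. The
#'   default is a fixed log-spaced ladder from 80 to 1200 cells.
#' @param dispersion negative-binomial size parameter (> 0).
#' @param effectRegions regions (names or indices) carrying the planted effect.
#' @param effectGroup group whose mean is shifted.
#' @param effectSize planted shift in units of within-group SD.
#' @param seed integer seed.
#' @return validated list of class \code{countSimConfig}.
#' @export
countSimConfig <- function(nPerGroup = 5L,
                           groups = c("saline", "R-ket", "S-ket"),
                           nRegions = 22L, regionNames = NULL,
                           baselineMean = NULL, dispersion = 8,
                           effectRegions = "IC", effectGroup = "R-ket",
                           effectSize = 0, seed = 1L) {
    nPerGroup <- as.integer(nPerGroup)
    nRegions <- as.integer(nRegions)
    stopIfNot(nPerGroup >= 2L, "nPerGroup must be >= 2 (got %d)", nPerGroup)
    stopIfNot(nRegions >= 1L, "nRegions must be >= 1")
    stopIfNot(length(groups) >= 1L && !anyDuplicated(groups),
              "groups must be distinct labels")
    if (is.null(regionNames)) regionNames <- defaultRegionNames(nRegions)
    stopIfNot(length(regionNames) == nRegions && !anyDuplicated(regionNames),
              "need %d distinct region names", nRegions)
    if (is.null(baselineMean))
        baselineMean <- round(exp(seq(log(80), log(1200),
                                      length.out = nRegions)))
    baselineMean <- rep_len(as.numeric(baselineMean), nRegions)
    stopIfNot(all(baselineMean > 0), "all baseline means must be > 0")
    stopIfNot(is.numeric(dispersion) && dispersion > 0,
              "dispersion must be > 0")
    if (is.numeric(effectRegions)) {
        stopIfNot(all(effectRegions >= 1 & effectRegions <= nRegions),
                  "effectRegions indices out of 1..%d", nRegions)
        effectRegions <- regionNames[effectRegions]
    }
    stopIfNot(all(effectRegions %in% regionNames),
              "effectRegions must be a subset of the region names")
    stopIfNot(effectGroup %in% groups, "effectGroup not among groups")
    structure(list(nPerGroup = nPerGroup, groups = groups,
                   nRegions = nRegions, regionNames = regionNames,
                   baselineMean = stats::setNames(baselineMean, regionNames),
                   dispersion = dispersion, effectRegions = effectRegions,
                   effectGroup = effectGroup, effectSize = effectSize,
                   seed = as.integer(seed)),
              class = "countSimConfig")
}

#' Simulate a brain-wide IEG cell-count table
#'
#' Draws a \linkS4class{CellCountTable} from the negative-binomial model in
#' \code{\link{countSimConfig}} and returns it with the ground truth of every
#' planted quantity. Identical configs (including seed) give identical tables.
#'
#' @param config a \code{\link{countSimConfig}}.
#' @return list with elements \code{table} (CellCountTable) and \code{truth}
#'   (list: effectRegions, effectGroup, effectSize, plantedShift in cells,
#'   baselineMean, dispersion, nominalSD).
#' @examples
#' sim <- simCellCounts(countSimConfig(effectSize = 2, seed = 7))
#' sim$truth$plantedShift
#' @export
simCellCounts <- function(config) {
    stopIfNot(inherits(config, "countSimConfig"),
              "config must come from countSimConfig()")
    nG <- length(config$groups)
    nA <- config$nPerGroup * nG
    group <- factor(rep(config$groups, each = config$nPerGroup),
                    levels = config$groups)
    animal <- sprintf("%s_%d", gsub("[^A-Za-z0-9]", "", rep(config$groups,
                      each = config$nPerGroup)), rep(seq_len(config$nPerGroup),
                      times = nG))
    mu <- config$baselineMean
    nominalSD <- sqrt(mu + mu^2 / config$dispersion)
    shift <- stats::setNames(numeric(config$nRegions), config$regionNames)
    shift[config$effectRegions] <- config$effectSize *
        nominalSD[config$effectRegions]
    # mean matrix, regions x animals
    muMat <- matrix(mu, nrow = config$nRegions, ncol = nA,
                    dimnames = list(config$regionNames, animal))
    muMat[, group == config$effectGroup] <-
        muMat[, group == config$effectGroup, drop = FALSE] + shift
    stopIfNot(all(muMat > 0),
              "planted effect drives a region mean non-positive")
    m <- withSeed(config$seed,
                  matrix(stats::rnbinom(length(muMat), mu = muMat,
                                        size = config$dispersion),
                         nrow = config$nRegions,
                         dimnames = dimnames(muMat)))
    list(table = CellCountTable(m, group = group,
                                groupLevels = config$groups),
         truth = list(effectRegions = config$effectRegions,
                      effectGroup = config$effectGroup,
                      effectSize = config$effectSize,
                      plantedShift = shift,
                      baselineMean = mu,
                      dispersion = config$dispersion,
                      nominalSD = nominalSD))
}
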