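# CSV dialects (comma-separated, UTF-8, dot decimal, mandatory header) for
# counts, coordinates, traces and event logs, with validating readers and
# exact-round-trip writers.

readCsvChecked <- function(path, need, what) {
    stopIfNot(file.exists(path), "%s file not found: %s", what, path)
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    miss <- setdiff(need, colnames(df))
    stopIfNot(!length(miss), "%s file %s: malformed header, missing column(s) %s",
              what, path, paste(miss, collapse = ", "))
    df
}

# data line i of a headered CSV sits on file line i + 1
csvLine <- function(i) i + 1L

#' Read a cell-count table
#'
#' Expects a header \code{animal_id,group,<region>,...}; every remaining
#' column is a region of nonnegative integer counts. Format errors name the
#' offending file line.
#'
#' @param path CSV path.
#' @param groupLevels declared group label set; defaults to order of first
#'   appearance.
#' @return a \linkS4class{CellCountTable}.
#' @export
readCounts <- function(path, groupLevels = NULL) {
    df <- readCsvChecked(path, c("animal_id", "group"), "counts")
    regions <- setdiff(colnames(df), c("animal_id", "group"))
    stopIfNot(length(regions) >= 1L, "counts file %s has no region columns",
              path)
    m <- as.matrix(df[, regions, drop = FALSE])
    suppressWarnings(storage.mode(m) <- "double")
    bad <- which(rowSums(!is.finite(m) | m < 0 |
                         abs(m - round(m)) > 1e-8) > 0)
    if (length(bad))
        stop(sprintf("counts file %s: invalid count at line %d",
                     path, csvLine(bad[1])), call. = FALSE)
    rownames(m) <- df$animal_id
    if (is.null(groupLevels)) groupLevels <- unique(df$group)
    message(sprintf("read %d animals x %d regions from %s",
                    nrow(m), length(regions), path))
    CellCountTable(t(m), group = df$group, groupLevels = groupLevels)
}

#' Write a cell-count table
#' @param table a \linkS4class{CellCountTable}.
#' @param path output CSV path.
#' @export
writeCounts <- function(table, path) {
    df <- data.frame(animal_id = animalIds(table),
                     group = as.character(groups(table)),
                     t(counts(table)), check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    invisible(path)
}

#' Read per-cell coordinates
#'
#' Header \code{animal_id,group,ap_mm,ml_mm,dv_mm}; coordinates in mm
#' relative to bregma.
#'
#' @param path CSV path.
#' @return a \linkS4class{CellCoordinateSet}.
#' @export
readCoords <- function(path) {
    df <- readCsvChecked(path, c("animal_id", "group", "ap_mm", "ml_mm",
                                 "dv_mm"), "coordinates")
    for (cc in c("ap_mm", "ml_mm", "dv_mm")) {
        bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cc]]))))
        if (length(bad))
            stop(sprintf("coordinates file %s: non-numeric %s at line %d",
                         path, cc, csvLine(bad[1])), call. = FALSE)
        df[[cc]] <- as.numeric(df[[cc]])
    }
    message(sprintf("read %d cells from %s", nrow(df), path))
    CellCoordinateSet(df[, c("animal_id", "group", "ap_mm", "ml_mm",
                             "dv_mm")])
}

#' Write per-cell coordinates
#' @param cells a \linkS4class{CellCoordinateSet}.
#' @param path output CSV path.
#' @export
writeCoords <- function(cells, path) {
    df <- cellCoords(cells)
    df$ap_mm <- fmtNum(df$ap_mm); df$ml_mm <- fmtNum(df$ml_mm)
    df$dv_mm <- fmtNum(df$dv_mm)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a photometry trace
#'
#' Header \code{time_s,fluorescence}. The baseline segment is declared either
#' directly via \code{baselineWindow} or through a YAML manifest with fields
#' \code{baseline_start_s} and \code{baseline_end_s} (and optionally
#' \code{rate}).
#'
#' @param path CSV path.
#' @param baselineWindow c(start, end) seconds.
#' @param manifest YAML manifest path (used when \code{baselineWindow} is
#'   NULL).
#' @param rate sampling rate; inferred from the time stamps when NULL.
#' @return a \linkS4class{PhotometryTrace}.
#' @export
readTrace <- function(path, baselineWindow = NULL, manifest = NULL,
                      rate = NULL) {
    df <- readCsvChecked(path, c("time_s", "fluorescence"), "trace")
    if (is.null(baselineWindow)) {
        stopIfNot(!is.null(manifest),
                  "either baselineWindow or a manifest is required")
        mf <- yaml::read_yaml(manifest)
        stopIfNot(all(c("baseline_start_s", "baseline_end_s") %in% names(mf)),
                  "manifest %s lacks baseline_start_s / baseline_end_s",
                  manifest)
        baselineWindow <- c(mf$baseline_start_s, mf$baseline_end_s)
        if (is.null(rate) && !is.null(mf$rate)) rate <- mf$rate
    }
    tm <- as.numeric(df$time_s)
    sig <- as.numeric(df$fluorescence)
    bad <- which(!is.finite(sig))
    if (length(bad))
        stop(sprintf("trace file %s: non-finite fluorescence at line %d",
                     path, csvLine(bad[1])), call. = FALSE)
    if (is.null(rate)) rate <- 1 / stats::median(diff(tm))
    message(sprintf("read %d samples (%.1f s at %g Hz) from %s",
                    length(tm), length(tm) / rate, rate, path))
    PhotometryTrace(tm, sig, rate, baselineWindow)
}

#' Write a raw photometry trace
#' @param trace a \linkS4class{PhotometryTrace}.
#' @param path output CSV path.
#' @export
writeTrace <- function(trace, path) {
    writeLines(c("time_s,fluorescence",
                 paste(fmtNum(trace@time), fmtNum(trace@signal), sep = ",")),
               path, useBytes = TRUE)
    invisible(path)
}

#' Write a z-scored trace
#' @param z a \linkS4class{ZTrace}.
#' @param path output CSV path.
#' @export
writeZTrace <- function(z, path) {
    writeLines(c("time_s,z",
                 paste(fmtNum(z@time), fmtNum(z@z), sep = ",")),
               path, useBytes = TRUE)
    invisible(path)
}

#' Read an investigation event log
#'
#' Header \code{onset_s,offset_s,label[,trial]}. Validation errors (offset
#' before onset, unordered or overlapping events) name the offending line.
#'
#' @param path CSV path.
#' @return an \linkS4class{EventLog}.
#' @export
readEvents <- function(path) {
    df <- readCsvChecked(path, c("onset_s", "offset_s", "label"), "events")
    on <- as.numeric(df$onset_s); off <- as.numeric(df$offset_s)
    bad <- which(!is.finite(on) | !is.finite(off) | off <= on)
    if (length(bad))
        stop(sprintf("events file %s: offset <= onset at line %d",
                     path, csvLine(bad[1])), call. = FALSE)
    if (is.unsorted(on, strictly = TRUE))
        stop(sprintf("events file %s: onsets not strictly increasing at line %d",
                     path, csvLine(which(diff(on) <= 0)[1] + 1L)),
             call. = FALSE)
    if (length(on) > 1L && any(on[-1L] < off[-length(off)]))
        stop(sprintf("events file %s: overlapping events at line %d", path,
                     csvLine(which(on[-1L] < off[-length(off)])[1] + 1L)),
             call. = FALSE)
    message(sprintf("read %d events from %s", nrow(df), path))
    ev <- data.frame(onset = on, offset = off, label = df$label)
    if ("trial" %in% colnames(df)) ev$trial <- df$trial
    EventLog(ev)
}

#' Write an investigation event log
#' @param log an \linkS4class{EventLog}.
#' @param path output CSV path.
#' @export
writeEvents <- function(log, path) {
    ev <- events(log)
    writeLines(c("onset_s,offset_s,label,trial",
                 paste(fmtNum(ev$onset), fmtNum(ev$offset), ev$label,
                       ev$trial, sep = ",")),
               path, useBytes = TRUE)
    invisible(path)
}
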