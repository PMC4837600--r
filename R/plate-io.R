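## Plate table reading/writing and batch fitting over wells.

detectDelimiter <- function(path) {
  first <- readLines(path, n = 1L)
  nComma <- lengths(regmatches(first, gregexpr(",", first, fixed = TRUE)))
  nTab <- lengths(regmatches(first, gregexpr("\t", first, fixed = TRUE)))
  if (nTab > nComma) "\t" else if (nComma > 0L) "," else
    stopWithClass("parseError",
                  "cannot auto-detect delimiter (no comma or tab in header); pass one explicitly")
}

#' Read a wide plate table (CSV/TSV)
#'
#' Reads a delimited file with a header row, one time column and one
#' column per well, into a [PlateTable-class]. Wells keep the file's
#' column order; rows are sorted by time if not already sorted. Numeric
#' parsing is locale-independent (decimal point only). The delimiter is
#' auto-detected between comma and tab from the header line; any other
#' delimiter must be passed explicitly -- silent mis-parsing is worse
#' than an error.
#'
#' @param path path to the file.
#' @param timeColumn name of the time column, matched case-insensitively
#'   (default `"time"`).
#' @param delimiter field delimiter; `NULL` (default) auto-detects
#'   comma/tab.
#' @param blankLabel optional well label of a media-only blank.
#' @return A [PlateTable-class].
#' @export
readPlateTable <- function(path, timeColumn = "time", delimiter = NULL,
                           blankLabel = NA_character_) {
  if (!file.exists(path))
    stopWithClass("ioError", "file not found: %s", path)
  if (is.null(delimiter)) delimiter <- detectDelimiter(path)
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = delimiter,
                      colClasses = "character", check.names = FALSE,
                      quote = "\"", comment.char = "", strip.white = TRUE),
    error = function(e) stopWithClass("parseError", "cannot parse %s: %s",
                                      path, conditionMessage(e))
  )
  if (ncol(raw) < 2L)
    stopWithClass("parseError",
                  "%s: need a time column plus at least one well column", path)
  hdr <- names(raw)
  ti <- which(tolower(hdr) == tolower(timeColumn))
  if (length(ti) == 0L)
    stopWithClass("parseError", "%s: time column '%s' not found (columns: %s)",
                  path, timeColumn, paste(hdr, collapse = ", "))
  if (length(ti) > 1L)
    stopWithClass("parseError", "%s: time column '%s' appears more than once",
                  path, timeColumn)
  wellNames <- hdr[-ti]
  if (anyDuplicated(wellNames))
    stopWithClass("parseError", "%s: duplicate well label '%s'",
                  path, wellNames[duplicated(wellNames)][1L])

  parseNumericColumn <- function(chr, colName) {
    num <- suppressWarnings(as.numeric(chr))
    bad <- which(!is.finite(num))
    if (length(bad))
      stopWithClass("parseError",
                    "%s: non-numeric value '%s' in column '%s', data row %d",
                    path, chr[bad[1L]], colName, bad[1L])
    num
  }
  times <- parseNumericColumn(raw[[ti]], hdr[ti])
  if (anyDuplicated(times))
    stopWithClass("parseError", "%s: duplicate time value %g",
                  path, times[duplicated(times)][1L])
  mat <- vapply(wellNames,
                function(w) parseNumericColumn(raw[[w]], w),
                numeric(nrow(raw)))
  mat <- matrix(mat, nrow = nrow(raw), dimnames = list(NULL, wellNames))
  ord <- order(times)
  plateTable(times[ord], mat[ord, , drop = FALSE], blankLabel = blankLabel)
}

#' Write a plate table to a delimited file
#'
#' Inverse of [readPlateTable()]: one time column followed by one column
#' per well, full double precision (17 significant digits) so a
#' write/read round trip reproduces the values exactly.
#'
#' @param plate a [PlateTable-class].
#' @param path output path.
#' @param timeColumn header name for the time column (default `"time"`).
#' @param delimiter field delimiter (default `","`).
#' @return Invisibly, `path`.
#' @export
writePlateTable <- function(plate, path, timeColumn = "time", delimiter = ",") {
  if (!is(plate, "PlateTable"))
    stopWithClass("invalidInput", "plate must be a PlateTable")
  fmt <- function(x) sprintf("%.17g", x)
  header <- paste(c(timeColumn, colnames(plate@readings)), collapse = delimiter)
  body <- apply(cbind(fmt(plate@times),
                      matrix(fmt(plate@readings), nrow = length(plate@times))),
                1L, paste, collapse = delimiter)
  ok <- tryCatch({ writeLines(c(header, body), path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stopWithClass("ioError", "cannot write %s", path)
  invisible(path)
}

summaryColumns <- c("well", "K", "K_se", "N0", "N0_se", "r", "r_se",
                    "sigma", "dof", "t_mid", "t_dt", "auc_l", "auc_e",
                    "converged", "note")

csvField <- function(x) {
  needsQuote <- grepl('[",\n]', x)
  x[needsQuote] <- paste0('"', gsub('"', '""', x[needsQuote]), '"')
  x
}

#' Write a per-well fit summary table
#'
#' Writes one CSV row per well with the columns `well, K, K_se, N0, N0_se,
#' r, r_se, sigma, dof, t_mid, t_dt, auc_l, auc_e, converged, note`, in
#' that order, at full double precision (17 significant digits).
#' Non-converged wells get empty metric cells and a populated `note`.
#'
#' @param results a list of [GrowthFitResult-class] objects (or a single
#'   one).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeSummary <- function(results, path) {
  if (is(results, "GrowthFitResult")) results <- list(results)
  if (!is.list(results) || length(results) == 0L ||
      !all(vapply(results, is, logical(1), "GrowthFitResult")))
    stopWithClass("invalidInput",
                  "results must be a non-empty list of GrowthFitResult objects")
  fmtNum <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  rows <- vapply(results, function(res) {
    m <- metricsRow(res)
    vals <- c(csvField(m$well),
              fmtNum(c(m$K, m$K_se, m$N0, m$N0_se, m$r, m$r_se, m$sigma,
                       m$dof, m$t_mid, m$t_dt, m$auc_l, m$auc_e)),
              if (m$converged) "true" else "false",
              csvField(m$note))
    paste(vals, collapse = ",")
  }, character(1))
  ok <- tryCatch({
    writeLines(c(paste(summaryColumns, collapse = ","), rows), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stopWithClass("ioError", "cannot write %s", path)
  invisible(path)
}

#' Fit every well of a plate
#'
#' Runs [summarizeGrowth()] on each non-blank well of a plate. Under
#' `"blank_series"` correction the blank well (the plate's `blankLabel`)
#' supplies the series subtracted from every other well. Per-well
#' failures surface as non-converged results, never exceptions.
#'
#' @param plate a [PlateTable-class].
#' @param correction background-correction mode (see [summarizeGrowth()]).
#' @param tAUCEnd optional end of the AUC window.
#' @param rMax growth-rate upper bound.
#' @param verbose emit a message per well (failures as warnings).
#' @return A named list of [GrowthFitResult-class], one per non-blank
#'   well, in plate column order.
#' @export
fitPlate <- function(plate, correction = c("min_value", "blank_series", "none"),
                     tAUCEnd = NULL, rMax = 20, verbose = FALSE) {
  if (!is(plate, "PlateTable"))
    stopWithClass("invalidInput", "plate must be a PlateTable")
  correction <- match.arg(correction)
  blank <- NULL
  if (correction == "blank_series") {
    if (is.na(plate@blankLabel))
      stopWithClass("invalidInput",
                    "blank_series correction requires the plate's blankLabel")
    blank <- plate@readings[, plate@blankLabel]
  }
  wells <- setdiff(colnames(plate@readings),
                   if (is.na(plate@blankLabel)) character(0) else plate@blankLabel)
  results <- lapply(wells, function(w) {
    res <- summarizeGrowth(plateWell(plate, w), correction = correction,
                           blank = blank, tAUCEnd = tAUCEnd, rMax = rMax)
    if (verbose) {
      if (converged(res))
        message(sprintf("well %s: fitted (K=%.4g, r=%.4g)",
                        w, res@params@K, res@params@r))
      else
        warning(sprintf("well %s: not converged (%s)", w, res@note),
                call. = FALSE, immediate. = TRUE)
    }
    res
  })
  names(results) <- wells
  results
}
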