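## Background/media correction applied to raw readings before fitting.

#' Subtract the per-well minimum reading (automatic background correction)
#'
#' Removes the media's contribution to absorbance by subtracting the
#' minimum observed reading of the well from all of its readings, so the
#' corrected series has minimum exactly 0. This is the automatic
#' correction mode and the package default; it requires no blank well and
#' makes fitted parameters invariant to any constant background offset.
#' The operation is idempotent.
#'
#' @param sample a [GrowthSample-class].
#' @return The sample with `corrected` filled in and
#'   `correctionApplied = "min_value"`.
#' @examples
#' s <- growthSample(0:2, c(0.09, 0.09, 0.5))
#' correctedReadings(subtractMinBackground(s))
#' @export
subtractMinBackground <- function(sample) {
  if (!is(sample, "GrowthSample"))
    stopWithClass("invalidInput", "sample must be a GrowthSample")
  if (length(sample@raw) == 0L)
    stopWithClass("invalidInput", "sample '%s' has no readings", sample@wellId)
  sample@corrected <- sample@raw - min(sample@raw)
  sample@correctionApplied <- "min_value"
  sample@hasNegative <- FALSE
  validObject(sample)
  sample
}

#' Subtract a blank-well (media-only) series
#'
#' Subtracts a media-only well's readings elementwise from the sample's
#' raw readings. Negative corrected values are retained, not clipped --
#' clipping would bias the information-poor but numerous early-time
#' points -- and flagged via `hasNegative`; the fit's N0 lower bound
#' absorbs them.
#'
#' @param sample a [GrowthSample-class].
#' @param blank numeric blank readings, same length as the sample's.
#' @return The sample with `corrected = raw - blank` and
#'   `correctionApplied = "blank_series"`.
#' @export
subtractBlankSeries <- function(sample, blank) {
  if (!is(sample, "GrowthSample"))
    stopWithClass("invalidInput", "sample must be a GrowthSample")
  checkFiniteNumeric(blank, "blank readings")
  if (length(blank) != length(sample@raw))
    stopWithClass("invalidInput",
                  "blank length (%d) does not match readings (%d)",
                  length(blank), length(sample@raw))
  sample@corrected <- sample@raw - blank
  sample@correctionApplied <- "blank_series"
  sample@hasNegative <- any(sample@corrected < 0)
  validObject(sample)
  sample
}

#' Apply a named background-correction mode
#'
#' Dispatch helper used by the batch and CLI layers: `"min_value"` calls
#' [subtractMinBackground()], `"blank_series"` calls
#' [subtractBlankSeries()] (requiring `blank`), `"none"` copies raw to
#' corrected unchanged.
#'
#' @param sample a [GrowthSample-class].
#' @param mode one of `"min_value"` (default), `"blank_series"`, `"none"`.
#' @param blank blank-well readings, required for `"blank_series"`.
#' @return The corrected sample.
#' @export
applyCorrection <- function(sample, mode = c("min_value", "blank_series", "none"),
                            blank = NULL) {
  mode <- match.arg(mode)
  switch(mode,
    min_value = subtractMinBackground(sample),
    blank_series = {
      if (is.null(blank))
        stopWithClass("invalidInput",
                      "blank_series correction requires a blank series")
      subtractBlankSeries(sample, blank)
    },
    none = {
      sample@corrected <- sample@raw
      sample@correctionApplied <- "none"
      sample@hasNegative <- any(sample@raw < 0)
      sample
    })
}
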