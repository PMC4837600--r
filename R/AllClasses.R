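#' @import methods
NULL

## Condition helper: classed errors so callers can distinguish failure modes
## (invalid input vs degenerate data vs undefined quantities) without parsing
## messages.
stopWithClass <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "microgrowthError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

checkFiniteNumeric <- function(x, what) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(!is.finite(x))) {
    stopWithClass("invalidInput", "%s must be finite numeric, got %s",
                  what, paste(utils::head(x, 3), collapse = ", "))
  }
  invisible(x)
}

#' LogisticParameters: the fitted logistic triple
#'
#' Holds the three parameters of the standard logistic growth equation
#' N(t) = K / (1 + ((K - N0)/N0) exp(-r t)): the carrying capacity `K`
#' (upper asymptote, in reading units), the intrinsic growth rate `r`
#' (inverse time units), and the initial population size `N0` (reading
#' units, the curve's value at t = 0). Units are inherited from the data
#' the parameters were fitted to; the package imposes no unit system.
#'
#' `N0 > K` (a declining curve) is mathematically permitted and flagged
#' downstream rather than rejected: least-squares fits on noisy flat wells
#' can land there and users need the flag, not a crash.
#'
#' @slot K numeric(1), carrying capacity, > 0.
#' @slot r numeric(1), intrinsic growth rate, finite.
#' @slot N0 numeric(1), initial population size, > 0.
#' @export
setClass("LogisticParameters",
  representation(K = "numeric", r = "numeric", N0 = "numeric"),
  validity = function(object) {
    msgs <- character()
    for (s in c("K", "r", "N0")) {
      v <- slot(object, s)
      if (length(v) != 1L || !is.finite(v))
        msgs <- c(msgs, sprintf("%s must be a single finite number", s))
    }
    if (length(msgs) == 0L) {
      if (object@K <= 0) msgs <- c(msgs, "K must be > 0")
      if (object@N0 <= 0) msgs <- c(msgs, "N0 must be > 0")
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' Construct a LogisticParameters object
#'
#' @param K carrying capacity (> 0).
#' @param r intrinsic growth rate (finite; > 0 for a growing population).
#' @param N0 initial population size (> 0).
#' @return A [LogisticParameters-class] object.
#' @examples
#' logisticParameters(K = 0.5, r = 1.2, N0 = 0.01)
#' @export
logisticParameters <- function(K, r, N0) {
  for (v in list(K = K, r = r, N0 = N0)) {
    if (!is.numeric(v) || length(v) != 1L)
      stopWithClass("invalidInput", "K, r, N0 must each be a single number")
  }
  if (!all(is.finite(c(K, r, N0))))
    stopWithClass("invalidInput", "K, r, N0 must all be finite")
  if (K <= 0 || N0 <= 0)
    stopWithClass("invalidInput", "K and N0 must be > 0 (got K=%g, N0=%g)", K, N0)
  new("LogisticParameters", K = K, r = r, N0 = N0)
}

#' GrowthSample: one well's time series
#'
#' A single well's time vector with its raw absorbance readings and, once a
#' background correction has been applied, the corrected readings used for
#' fitting. `correctionApplied` records which correction produced
#' `corrected` ("none", "min_value", or "blank_series"); `hasNegative` is
#' raised when blank-series subtraction leaves negative values (they are
#' kept, not clipped; the fit's N0 lower bound absorbs them).
#'
#' @slot wellId character(1) label.
#' @slot times strictly increasing numeric time vector.
#' @slot raw numeric readings, same length as `times`.
#' @slot corrected corrected readings (length 0 until a correction is applied).
#' @slot correctionApplied one of "none", "min_value", "blank_series".
#' @slot hasNegative logical(1), TRUE if `corrected` contains negatives.
#' @export
setClass("GrowthSample",
  representation(
    wellId = "character", times = "numeric", raw = "numeric",
    corrected = "numeric", correctionApplied = "character",
    hasNegative = "logical"
  ),
  prototype(corrected = numeric(0), correctionApplied = "none",
            hasNegative = FALSE),
  validity = function(object) {
    msgs <- character()
    if (length(object@wellId) != 1L) msgs <- c(msgs, "wellId must be length 1")
    if (length(object@times) != length(object@raw))
      msgs <- c(msgs, "times and raw must have equal length")
    if (length(object@times) >= 2L && any(diff(object@times) <= 0))
      msgs <- c(msgs, "times must be strictly increasing")
    if (any(!is.finite(object@raw))) msgs <- c(msgs, "raw readings must be finite")
    if (length(object@corrected) &&
        length(object@corrected) != length(object@raw))
      msgs <- c(msgs, "corrected must match raw in length")
    if (!object@correctionApplied %in% c("none", "min_value", "blank_series"))
      msgs <- c(msgs, "unknown correctionApplied value")
    if (length(msgs)) msgs else TRUE
  }
)

#' Construct a GrowthSample
#'
#' @param times strictly increasing numeric time vector.
#' @param raw absorbance/cell-count readings at those times.
#' @param wellId well label (default "sample").
#' @return A [GrowthSample-class] object with no correction applied.
#' @examples
#' growthSample(times = 0:5, raw = c(0.1, 0.1, 0.2, 0.4, 0.5, 0.5), wellId = "A1")
#' @export
growthSample <- function(times, raw, wellId = "sample") {
  checkFiniteNumeric(times, "times")
  checkFiniteNumeric(raw, "raw readings")
  if (length(times) != length(raw))
    stopWithClass("invalidInput", "times (%d) and raw (%d) differ in length",
                  length(times), length(raw))
  if (length(times) >= 2L && any(diff(times) <= 0))
    stopWithClass("invalidInput", "times must be strictly increasing")
  new("GrowthSample", wellId = as.character(wellId)[1L],
      times = as.numeric(times), raw = as.numeric(raw))
}

#' GrowthFitResult: fitted parameters, diagnostics and derived metrics
#'
#' The complete per-well output of a logistic fit: the parameter estimates,
#' Jacobian-based standard errors, residual standard error `sigma` =
#' sqrt(RSS / dof) with `dof` = n - 3 residual degrees of freedom, the
#' convergence status, and the derived metrics -- inflection time `tMid`
#' (where N = K/2), fastest doubling time `tDoubling` = ln(2)/r, the
#' closed-form logistic AUC and the trapezoid empirical AUC over the fit
#' window. Non-converged fits carry `converged = FALSE`, a diagnostic
#' `note`, and `NA` metrics; in batch contexts non-convergence is data,
#' never an exception.
#'
#' @slot wellId character(1) label.
#' @slot params fitted [LogisticParameters-class] (slots are `NA`-free only
#'   when `converged`).
#' @slot stderr named numeric: standard errors for K, r, N0 (`NA` when the
#'   Jacobian is rank-deficient).
#' @slot sigma residual standard error (reading units).
#' @slot dof residual degrees of freedom (n - 3).
#' @slot converged logical(1).
#' @slot note free-text diagnostic ("" on clean convergence).
#' @slot tMid time at which N = K/2 (`NA` when N0 >= K).
#' @slot tDoubling fastest doubling time ln(2)/r.
#' @slot aucLogistic closed-form AUC of the fitted curve over the window.
#' @slot aucEmpirical trapezoid AUC of the corrected readings over the window.
#' @slot window numeric(2), the AUC window (start, end).
#' @export
setClass("GrowthFitResult",
  representation(
    wellId = "character", params = "ANY", stderr = "numeric",
    sigma = "numeric", dof = "numeric", converged = "logical",
    note = "character", tMid = "numeric", tDoubling = "numeric",
    aucLogistic = "numeric", aucEmpirical = "numeric", window = "numeric"
  ),
  prototype(
    params = NULL,
    stderr = c(K = NA_real_, r = NA_real_, N0 = NA_real_),
    sigma = NA_real_, dof = NA_real_, converged = FALSE, note = "",
    tMid = NA_real_, tDoubling = NA_real_, aucLogistic = NA_real_,
    aucEmpirical = NA_real_, window = c(NA_real_, NA_real_)
  ),
  validity = function(object) {
    msgs <- character()
    if (length(object@converged) != 1L)
      msgs <- c(msgs, "converged must be length 1")
    if (isTRUE(object@converged)) {
      if (is.null(object@params))
        msgs <- c(msgs, "converged fit must carry parameters")
      if (is.finite(object@sigma) && object@sigma < 0)
        msgs <- c(msgs, "sigma must be >= 0")
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' PlateTable: a plate's shared time grid and per-well readings
#'
#' Wide representation of one plate run: a single strictly increasing time
#' vector shared by all wells, and a readings matrix with one column per
#' well (rows are time points, columns carry unique well labels). An
#' optional `blankLabel` designates a media-only well for blank-series
#' correction.
#'
#' @slot times strictly increasing numeric vector.
#' @slot readings numeric matrix, `length(times)` rows, one named column
#'   per well.
#' @slot blankLabel character(1) well label of a media-only blank, or
#'   `NA_character_`.
#' @export
setClass("PlateTable",
  representation(times = "numeric", readings = "matrix",
                 blankLabel = "character"),
  prototype(blankLabel = NA_character_),
  validity = function(object) {
    msgs <- character()
    if (nrow(object@readings) != length(object@times))
      msgs <- c(msgs, "readings must have one row per time point")
    if (is.null(colnames(object@readings)) ||
        anyDuplicated(colnames(object@readings)))
      msgs <- c(msgs, "well labels must be present and unique")
    if (length(object@times) >= 2L && any(diff(object@times) <= 0))
      msgs <- c(msgs, "times must be strictly increasing")
    if (!is.na(object@blankLabel) &&
        !object@blankLabel %in% colnames(object@readings))
      msgs <- c(msgs, "blankLabel is not a well of this plate")
    if (length(msgs)) msgs else TRUE
  }
)

#' Construct a PlateTable
#'
#' @param times strictly increasing numeric time vector.
#' @param readings numeric matrix (time points x wells) with unique column
#'   names, or a named list of equal-length reading vectors.
#' @param blankLabel optional label of a media-only blank well.
#' @return A [PlateTable-class] object.
#' @export
plateTable <- function(times, readings, blankLabel = NA_character_) {
  checkFiniteNumeric(times, "times")
  if (is.list(readings)) {
    if (is.null(names(readings)) || any(names(readings) == ""))
      stopWithClass("invalidInput", "readings list must be fully named")
    lens <- lengths(readings)
    if (any(lens != length(times)))
      stopWithClass("invalidInput",
                    "all reading vectors must match times in length")
    readings <- do.call(cbind, lapply(readings, as.numeric))
  }
  readings <- as.matrix(readings)
  storage.mode(readings) <- "double"
  new("PlateTable", times = as.numeric(times), readings = readings,
      blankLabel = as.character(blankLabel)[1L])
}

#' SyntheticCurveSpec: ground truth for the growth-curve generator
#'
#' Ground-truth logistic parameters plus acquisition and noise settings for
#' one simulated well: a regular sampling grid from `tStart` to `tEnd` in
#' steps of `dt`, a constant additive `background` offset standing in for
#' media absorbance, and additive Gaussian reading noise of standard
#' deviation `noiseSd`, drawn from a seeded generator so every curve is
#' reproducible.
#'
#' @slot params true [LogisticParameters-class].
#' @slot tStart,tEnd sampling window (time units; `tEnd > tStart`).
#' @slot dt sampling interval (> 0).
#' @slot noiseSd additive Gaussian noise standard deviation (>= 0).
#' @slot background constant additive offset (>= 0).
#' @slot seed integer RNG seed.
#' @export
setClass("SyntheticCurveSpec",
  representation(params = "LogisticParameters", tStart = "numeric",
                 tEnd = "numeric", dt = "numeric", noiseSd = "numeric",
                 background = "numeric", seed = "integer"),
  validity = function(object) {
    msgs <- character()
    if (object@dt <= 0) msgs <- c(msgs, "dt must be > 0")
    if (object@tEnd <= object@tStart) msgs <- c(msgs, "tEnd must exceed tStart")
    if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
    if (object@background < 0) msgs <- c(msgs, "background must be >= 0")
    if (length(msgs)) msgs else TRUE
  }
)
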