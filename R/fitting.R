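## Nonlinear least-squares estimation of (K, r, N0) and metric assembly.
## The Levenberg-Marquardt step is minpack.lm::nlsLM with box constraints;
## everything around it (starting values, degeneracy screens, diagnostics,
## derived metrics) is defined here.

defaultFitControl <- function(maxIter = 1000L, ftol = 1e-10, ptol = 1e-10) {
  minpack.lm::nls.lm.control(maxiter = maxIter, ftol = ftol, ptol = ptol)
}

#' Starting values for the logistic fit
#'
#' Heuristic initial parameters: K0 is the largest observed reading; N0_0
#' is the first reading, floored at epsilon = 1e-6 * max(values) to guard
#' zeros created by minimum-subtraction; r0 is the slope of a
#' least-squares line through log(values + epsilon) versus time over the
#' points between 10 and 50 percent of the maximum (the near-exponential
#' phase), falling back to 1 per time unit when fewer than 3 such points
#' exist or the slope is not positive. All outputs are finite and
#' positive.
#'
#' @param times strictly increasing time vector (>= 4 points).
#' @param values corrected readings.
#' @return A [LogisticParameters-class] starting triple.
#' @export
initialGuess <- function(times, values) {
  checkFiniteNumeric(times, "times"); checkFiniteNumeric(values, "values")
  if (length(times) != length(values))
    stopWithClass("invalidInput", "times and values differ in length")
  if (length(times) < 4L)
    stopWithClass("invalidInput", "need at least 4 points for a starting guess")
  if (any(diff(times) <= 0))
    stopWithClass("invalidInput", "times must be strictly increasing")
  maxv <- max(values)
  if (maxv <= 0)
    stopWithClass("degenerateSample",
                  "no positive readings: cannot form a starting guess")
  eps <- 1e-6 * maxv
  K0 <- maxv
  N00 <- max(values[1L], eps)
  idx <- which(values >= 0.1 * maxv & values <= 0.5 * maxv)
  r0 <- 1
  if (length(idx) >= 3L) {
    sl <- stats::coef(stats::lm(log(values[idx] + eps) ~ times[idx]))[[2L]]
    if (is.finite(sl) && sl > 0) r0 <- sl
  }
  logisticParameters(K = K0, r = r0, N0 = N00)
}

nonConvergedResult <- function(wellId, note, window = c(NA_real_, NA_real_)) {
  new("GrowthFitResult", wellId = wellId, converged = FALSE, note = note,
      window = window)
}

#' Fit the logistic growth model to one well
#'
#' Estimates (K, r, N0) by bounded Levenberg-Marquardt nonlinear least
#' squares, minimising the sum of squared residuals between the corrected
#' readings and the logistic curve. Box constraints keep the search in the
#' biologically meaningful region: K in (0, 10 max(y)\], r in (0, rMax\],
#' N0 in \[1e-6 max(y), max(y)\]; for well-behaved data the constrained
#' optimum coincides with the unconstrained one, while flat or pathological
#' wells are prevented from diverging. Convergence tolerances are a
#' relative cost tolerance and parameter tolerance of 1e-10 with at most
#' 1000 iterations.
#'
#' Degenerate inputs (constant, all-zero, or monotone-decreasing-only
#' signal) and optimizer failures yield a result with `converged = FALSE`
#' and an explanatory `note` -- never an exception, so one bad well cannot
#' kill a plate run. Standard errors come from the Jacobian-based
#' covariance estimate sigma^2 (J'J)^-1 and are reported as `NA` (absent,
#' not zero) when the Jacobian is rank-deficient.
#'
#' @param sample a [GrowthSample-class] with corrected readings present
#'   (apply a correction first, or use [summarizeGrowth()]).
#' @param rMax upper bound for the growth rate, per time unit (default 20);
#'   caps pathological step-function fits.
#' @param tAUCEnd end of the AUC window; default the last time point.
#' @param control a [minpack.lm::nls.lm.control()] list.
#' @return A [GrowthFitResult-class].
#' @examples
#' spec <- syntheticCurveSpec(K = 0.6, r = 1, N0 = 0.01, noiseSd = 0, background = 0)
#' fitLogistic(subtractMinBackground(generateCurve(spec)))
#' @export
fitLogistic <- function(sample, rMax = 20, tAUCEnd = NULL,
                        control = defaultFitControl()) {
  if (!is(sample, "GrowthSample"))
    stopWithClass("invalidInput", "sample must be a GrowthSample")
  if (length(sample@corrected) == 0L)
    stopWithClass("invalidInput",
                  "well '%s': corrected readings absent; apply a background correction first",
                  sample@wellId)
  t <- sample@times
  y <- sample@corrected
  n <- length(y)
  if (n < 5L)
    stopWithClass("invalidInput",
                  "well '%s': need at least 5 points to fit, got %d",
                  sample@wellId, n)
  if (is.null(tAUCEnd)) tAUCEnd <- t[n]
  if (tAUCEnd > t[n] || tAUCEnd < t[1L])
    stopWithClass("invalidInterval",
                  "AUC window end %g outside the data range [%g, %g]",
                  tAUCEnd, t[1L], t[n])
  window <- c(t[1L], tAUCEnd)

  ## degeneracy screens: these are data conditions, not errors
  if (diff(range(y)) == 0)
    return(nonConvergedResult(sample@wellId, "constant signal", window))
  if (max(y) <= 0)
    return(nonConvergedResult(sample@wellId, "no positive signal", window))
  if (all(diff(y) <= 0))
    return(nonConvergedResult(sample@wellId,
                              "monotone decreasing signal", window))

  guess <- tryCatch(initialGuess(t, y), microgrowthError = function(e) NULL)
  if (is.null(guess))
    return(nonConvergedResult(sample@wellId, "degenerate sample", window))

  maxy <- max(y)
  eps <- 1e-6 * maxy
  lower <- c(K = .Machine$double.xmin, r = .Machine$double.xmin, N0 = eps)
  upper <- c(K = 10 * maxy, r = rMax, N0 = maxy)
  start <- c(K = guess@K, r = min(guess@r, rMax), N0 = min(guess@N0, maxy))
  start <- pmin(pmax(start, lower), upper)

  dat <- data.frame(.t = t, .y = y)
  runFit <- function(start, upper) tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      .y ~ K / (1 + ((K - N0) / N0) * exp(-r * .t)),
      data = dat, start = as.list(start),
      lower = lower, upper = upper, control = control
    )),
    error = function(e) e
  )
  fit <- runFit(start, upper)
  ## A curve still far from saturation at the last reading carries the
  ## K information in its curvature, not its maximum: when the fit lands
  ## on the K ceiling, raise the ceiling (up to 1e9 max(y)) and refit
  ## from the constrained solution rather than report a clipped K.
  expansions <- 0L
  while (!inherits(fit, "error") && isTRUE(fit$convInfo$isConv) &&
         stats::coef(fit)[["K"]] >= 0.999 * upper[["K"]] &&
         expansions < 4L) {
    upper[["K"]] <- upper[["K"]] * 100
    fit <- runFit(pmin(stats::coef(fit)[c("K", "r", "N0")], upper), upper)
    expansions <- expansions + 1L
  }
  if (inherits(fit, "error"))
    return(nonConvergedResult(
      sample@wellId, sprintf("optimizer failure: %s", conditionMessage(fit)),
      window))
  if (!isTRUE(fit$convInfo$isConv))
    return(nonConvergedResult(
      sample@wellId,
      sprintf("did not converge: %s", fit$convInfo$stopMessage), window))

  cf <- stats::coef(fit)
  params <- logisticParameters(K = cf[["K"]], r = cf[["r"]], N0 = cf[["N0"]])
  rss <- sum(stats::residuals(fit)^2)
  dof <- n - 3L
  sigma <- sqrt(rss / dof)

  se <- c(K = NA_real_, r = NA_real_, N0 = NA_real_)
  note <- ""
  seTry <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                    error = function(e) NULL)
  if (is.null(seTry) || any(!is.finite(seTry))) {
    note <- "standard errors unavailable (rank-deficient Jacobian)"
  } else {
    se[names(seTry)] <- seTry
  }
  if (params@N0 >= params@K)
    note <- paste(c(note[nzchar(note)],
                    "flagged: N0 >= K (declining or flat fit)"),
                  collapse = "; ")

  new("GrowthFitResult",
      wellId = sample@wellId, params = params, stderr = se,
      sigma = sigma, dof = as.numeric(dof), converged = TRUE, note = note,
      tMid = inflectionTime(params),
      tDoubling = if (params@r > 0) log(2) / params@r else NA_real_,
      aucLogistic = logisticAUC(params, window[1L], window[2L]),
      aucEmpirical = empiricalAUC(t, y, tEnd = window[2L]),
      window = window)
}

#' Summarize one growth curve: correction, fit and metrics in one call
#'
#' The single-well front door: applies the configured background
#' correction to the raw readings, fits the logistic model, and populates
#' the full metric set. The AUC window runs from the first time point to
#' `tAUCEnd` when given, otherwise over the full record. Fitting failures
#' propagate as non-converged results, not exceptions.
#'
#' @param sample a [GrowthSample-class] (raw readings suffice).
#' @param correction background-correction mode: `"min_value"` (default),
#'   `"blank_series"`, or `"none"`.
#' @param blank blank-well readings, required when
#'   `correction = "blank_series"`.
#' @param tAUCEnd optional end of the AUC window (must lie within the
#'   record).
#' @param rMax upper bound for the growth rate (default 20 per time unit).
#' @return A [GrowthFitResult-class].
#' @examples
#' spec <- syntheticCurveSpec(K = 0.5, r = 1.1, N0 = 0.008, seed = 7)
#' summarizeGrowth(generateCurve(spec))
#' @export
summarizeGrowth <- function(sample,
                            correction = c("min_value", "blank_series", "none"),
                            blank = NULL, tAUCEnd = NULL, rMax = 20) {
  correction <- match.arg(correction)
  corrected <- applyCorrection(sample, correction, blank = blank)
  fitLogistic(corrected, rMax = rMax, tAUCEnd = tAUCEnd)
}
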