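## Pure mathematical core: logistic trajectory, doubling time, both AUCs.

#' Evaluate the logistic growth curve
#'
#' Computes N(t) = K / (1 + A exp(-r t)) with A = (K - N0)/N0, the standard
#' logistic population-growth equation used throughout ecology and
#' evolution. For 0 < N0 < K and r > 0 the curve rises monotonically from
#' N0 at t = 0 towards the carrying capacity K, crossing K/2 at its
#' inflection point. Negative t is permitted (extrapolation before the
#' first reading).
#'
#' @param params a [LogisticParameters-class] object.
#' @param t numeric vector of times (finite; any consistent unit).
#' @return N(t), same length as `t`, in the units of `K`.
#' @examples
#' p <- logisticParameters(K = 0.5, r = 0.5, N0 = 0.01)
#' logisticValue(p, c(0, 5, 10, 20))
#' @export
logisticValue <- function(params, t) {
  if (!is(params, "LogisticParameters"))
    stopWithClass("invalidInput", "params must be a LogisticParameters object")
  validObject(params)
  if (!is.numeric(t) || length(t) == 0L || any(!is.finite(t)))
    stopWithClass("invalidInput", "t must be finite numeric")
  A <- (params@K - params@N0) / params@N0
  params@K / (1 + A * exp(-params@r * t))
}

#' Fastest doubling time of a population
#'
#' The fastest possible doubling (generation) time under unrestricted
#' growth, ln(2) / r, attained far from the carrying capacity. The result
#' inherits the inverse of `r`'s unit: an r in 1/h gives hours.
#'
#' @param r intrinsic growth rate(s), > 0.
#' @return ln(2) / r, same length as `r`.
#' @examples
#' doublingTime(log(2))   # 1 time unit
#' doublingTime(0.9)      # ~46 min when r is per hour
#' @export
doublingTime <- function(r) {
  if (!is.numeric(r) || length(r) == 0L)
    stopWithClass("invalidInput", "r must be numeric")
  if (any(!is.finite(r)))
    stopWithClass("nonFiniteGrowthRate",
                  "doubling time undefined: growth rate is not finite")
  if (any(r <= 0))
    stopWithClass("nonpositiveGrowthRate",
                  "doubling time undefined for r <= 0 (got %g)", min(r))
  log(2) / r
}

## Antiderivative of the logistic curve: F(tau) = (K/r) ln(e^{r tau} + A).
## ln(e^x + A) is computed by a log-sum-exp guard so that r*tau far beyond
## ~709 (where exp overflows) stays finite: for A > 0,
## ln(e^x + A) = max(x, ln A) + log1p(exp(-|x - ln A|)).
logisticAntiderivative <- function(K, r, N0, tau) {
  A <- (K - N0) / N0
  x <- r * tau
  if (A == 0) return(K * tau)            # constant integrand N == K
  if (A > 0) {
    lnA <- log(A)
    m <- pmax(x, lnA)
    (K / r) * (m + log1p(exp(-abs(x - lnA))))
  } else {
    ## N0 > K: A in (-1, 0); e^x + A > 0 whenever x > ln(-A) (always true
    ## for tau >= 0, r > 0). Direct evaluation; overflow-guarded via the
    ## same decomposition ln(e^x + A) = x + log1p(A e^{-x}).
    (K / r) * (x + log1p(A * exp(-x)))
  }
}

#' Closed-form area under the fitted logistic curve
#'
#' Evaluates the definite integral of the logistic curve N(t) over
#' \[`tStart`, `tEnd`\] analytically, using the antiderivative
#' (K/r) ln(e^(r t) + A) with A = (K - N0)/N0. The integral combines K, r
#' and N0 into a single summary of growth over a window; its units are
#' reading units x time units. Large r t is handled by a log-sum-exp
#' guard so long runs in fine time units do not overflow. The degenerate
#' cases r = 0 or K = N0 (constant curve) integrate exactly.
#'
#' @param params a [LogisticParameters-class] object.
#' @param tStart,tEnd integration window, `tEnd >= tStart`.
#' @return The area, a single number.
#' @examples
#' p <- logisticParameters(K = 0.8, r = 1.2, N0 = 0.02)
#' logisticAUC(p, 0, 24)
#' @export
logisticAUC <- function(params, tStart, tEnd) {
  if (!is(params, "LogisticParameters"))
    stopWithClass("invalidInput", "params must be a LogisticParameters object")
  validObject(params)
  checkFiniteNumeric(tStart, "tStart"); checkFiniteNumeric(tEnd, "tEnd")
  if (length(tStart) != 1L || length(tEnd) != 1L)
    stopWithClass("invalidInput", "tStart and tEnd must be single times")
  if (tEnd < tStart)
    stopWithClass("invalidInterval",
                  "tEnd (%g) must not precede tStart (%g)", tEnd, tStart)
  if (tEnd == tStart) return(0)
  K <- params@K; r <- params@r; N0 <- params@N0
  if (r == 0 || K == N0) {
    ## flat curve at N0 (r = 0) or at K (= N0)
    return(N0 * (tEnd - tStart))
  }
  logisticAntiderivative(K, r, N0, tEnd) -
    logisticAntiderivative(K, r, N0, tStart)
}

#' Empirical (trapezoid) area under observed readings
#'
#' Sums the areas of the trapezoids formed by connecting consecutive data
#' points, from the first time point up to `tEnd` -- the non-parametric
#' counterpart to [logisticAUC()]. When `tEnd` falls between two sample
#' points the final trapezoid is truncated by linear interpolation to
#' `tEnd`, consistent with the trapezoid geometry.
#'
#' @param times strictly increasing numeric time vector (>= 2 points).
#' @param values readings at those times (same length).
#' @param tEnd end of the integration window; defaults to the last time
#'   point, and must not exceed it.
#' @return The trapezoid-rule area.
#' @examples
#' empiricalAUC(times = c(0, 1, 2), values = c(1, 1, 1))       # 2
#' empiricalAUC(times = c(0, 1, 2), values = c(0, 1, 2), tEnd = 1.5)
#' @export
empiricalAUC <- function(times, values, tEnd = NULL) {
  checkFiniteNumeric(times, "times"); checkFiniteNumeric(values, "values")
  if (length(times) != length(values))
    stopWithClass("invalidInput", "times and values differ in length")
  if (any(diff(times) <= 0))
    stopWithClass("invalidInput", "times must be strictly increasing")
  if (is.null(tEnd)) tEnd <- times[length(times)]
  checkFiniteNumeric(tEnd, "tEnd")
  if (tEnd > times[length(times)])
    stopWithClass("invalidInterval",
                  "tEnd (%g) lies beyond the last time point (%g)",
                  tEnd, times[length(times)])
  keep <- times <= tEnd
  if (sum(keep) < 2L && !(sum(keep) >= 1L && tEnd > times[1L]))
    stopWithClass("insufficientData",
                  "need at least 2 points at or before tEnd = %g", tEnd)
  t2 <- times[keep]; v2 <- values[keep]
  area <- if (length(t2) >= 2L)
    sum(0.5 * (v2[-1L] + v2[-length(v2)]) * diff(t2)) else 0
  ## partial final trapezoid when tEnd falls between samples
  if (tEnd > t2[length(t2)]) {
    i <- length(t2)
    vEnd <- values[i] + (values[i + 1L] - values[i]) *
      (tEnd - times[i]) / (times[i + 1L] - times[i])
    area <- area + 0.5 * (values[i] + vEnd) * (tEnd - times[i])
  }
  area
}

#' Inflection time of the logistic curve
#'
#' The time at which the population reaches half its carrying capacity,
#' t_mid = ln((K - N0)/N0) / r, the curve's inflection point. Undefined
#' (`NA`) when N0 >= K, where the curve has no interior inflection.
#'
#' @param params a [LogisticParameters-class] object.
#' @return The inflection time, or `NA` when N0 >= K or r = 0.
#' @export
inflectionTime <- function(params) {
  if (!is(params, "LogisticParameters"))
    stopWithClass("invalidInput", "params must be a LogisticParameters object")
  if (params@N0 >= params@K || params@r == 0) return(NA_real_)
  log((params@K - params@N0) / params@N0) / params@r
}
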