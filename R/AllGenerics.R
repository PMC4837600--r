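## Generics and accessors. Slot access from user code goes through these.

#' @describeIn LogisticParameters-class carrying capacity accessor
#' @param object a package object
#' @export
setGeneric("carryingCapacity", function(object) standardGeneric("carryingCapacity"))

#' @describeIn LogisticParameters-class intrinsic growth rate accessor
#' @export
setGeneric("growthRate", function(object) standardGeneric("growthRate"))

#' @describeIn LogisticParameters-class initial population size accessor
#' @export
setGeneric("initialPopulation", function(object) standardGeneric("initialPopulation"))

#' @export
setMethod("carryingCapacity", "LogisticParameters", function(object) object@K)
#' @export
setMethod("growthRate", "LogisticParameters", function(object) object@r)
#' @export
setMethod("initialPopulation", "LogisticParameters", function(object) object@N0)

#' @describeIn GrowthSample-class time vector accessor
#' @param x a package object
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))
#' @export
setMethod("sampleTimes", "GrowthSample", function(x) x@times)
#' @export
setMethod("sampleTimes", "PlateTable", function(x) x@times)

#' @describeIn GrowthSample-class raw readings accessor
#' @export
setGeneric("rawReadings", function(x) standardGeneric("rawReadings"))
#' @export
setMethod("rawReadings", "GrowthSample", function(x) x@raw)

#' @describeIn GrowthSample-class corrected readings (errors if no
#'   correction has been applied)
#' @export
setGeneric("correctedReadings", function(x) standardGeneric("correctedReadings"))
#' @export
setMethod("correctedReadings", "GrowthSample", function(x) {
  if (length(x@corrected) == 0L)
    stopWithClass("invalidInput",
                  "no background correction has been applied to well '%s'",
                  x@wellId)
  x@corrected
})

#' @describeIn GrowthSample-class well label accessor
#' @export
setGeneric("wellId", function(x) standardGeneric("wellId"))
#' @export
setMethod("wellId", "GrowthSample", function(x) x@wellId)
#' @export
setMethod("wellId", "GrowthFitResult", function(x) x@wellId)

#' @describeIn PlateTable-class well labels, in plate column order
#' @export
setGeneric("wellLabels", function(x) standardGeneric("wellLabels"))
#' @export
setMethod("wellLabels", "PlateTable", function(x) colnames(x@readings))

#' @describeIn PlateTable-class extract one well as a [GrowthSample-class]
#' @param well well label
#' @export
setGeneric("plateWell", function(x, well) standardGeneric("plateWell"))
#' @export
setMethod("plateWell", "PlateTable", function(x, well) {
  if (!well %in% colnames(x@readings))
    stopWithClass("invalidInput", "well '%s' not found on plate", well)
  growthSample(x@times, x@readings[, well], wellId = well)
})

#' @describeIn GrowthFitResult-class fitted parameters (NULL when not
#'   converged)
#' @export
setGeneric("fittedParameters", function(x) standardGeneric("fittedParameters"))
#' @export
setMethod("fittedParameters", "GrowthFitResult", function(x) x@params)

#' @describeIn GrowthFitResult-class convergence flag
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))
#' @export
setMethod("converged", "GrowthFitResult", function(x) x@converged)

#' @describeIn GrowthFitResult-class one-row data.frame of all metrics
#'   (the row written by [writeSummary()])
#' @export
setGeneric("metricsRow", function(x) standardGeneric("metricsRow"))
#' @export
setMethod("metricsRow", "GrowthFitResult", function(x) {
  p <- x@params
  data.frame(
    well = x@wellId,
    K = if (is.null(p)) NA_real_ else p@K,
    K_se = unname(x@stderr["K"]),
    N0 = if (is.null(p)) NA_real_ else p@N0,
    N0_se = unname(x@stderr["N0"]),
    r = if (is.null(p)) NA_real_ else p@r,
    r_se = unname(x@stderr["r"]),
    sigma = x@sigma, dof = x@dof, t_mid = x@tMid, t_dt = x@tDoubling,
    auc_l = x@aucLogistic, auc_e = x@aucEmpirical,
    converged = x@converged, note = x@note,
    stringsAsFactors = FALSE
  )
})

setMethod("show", "LogisticParameters", function(object) {
  cat(sprintf("LogisticParameters: K = %g, r = %g, N0 = %g\n",
              object@K, object@r, object@N0))
})

setMethod("show", "GrowthSample", function(object) {
  cat(sprintf("GrowthSample '%s': %d points, t in [%g, %g], correction: %s%s\n",
              object@wellId, length(object@times),
              if (length(object@times)) min(object@times) else NA,
              if (length(object@times)) max(object@times) else NA,
              object@correctionApplied,
              if (isTRUE(object@hasNegative)) " (negatives present)" else ""))
})

setMethod("show", "GrowthFitResult", function(object) {
  if (object@converged) {
    p <- object@params
    cat(sprintf("GrowthFitResult '%s' (converged)\n", object@wellId))
    cat(sprintf("  K = %.6g (se %.3g)  r = %.6g (se %.3g)  N0 = %.6g (se %.3g)\n",
                p@K, object@stderr["K"], p@r, object@stderr["r"],
                p@N0, object@stderr["N0"]))
    cat(sprintf("  sigma = %.4g on %d dof;  t_mid = %.4g,  t_dt = %.4g\n",
                object@sigma, as.integer(object@dof), object@tMid,
                object@tDoubling))
    cat(sprintf("  AUC (logistic) = %.6g,  AUC (empirical) = %.6g on [%g, %g]\n",
                object@aucLogistic, object@aucEmpirical,
                object@window[1], object@window[2]))
    if (nzchar(object@note)) cat("  note:", object@note, "\n")
  } else {
    cat(sprintf("GrowthFitResult '%s' (NOT converged): %s\n",
                object@wellId, object@note))
  }
})

setMethod("show", "PlateTable", function(object) {
  cat(sprintf("PlateTable: %d wells x %d time points, t in [%g, %g]%s\n",
              ncol(object@readings), length(object@times),
              min(object@times), max(object@times),
              if (!is.na(object@blankLabel))
                sprintf(", blank = '%s'", object@blankLabel) else ""))
})

setMethod("show", "SyntheticCurveSpec", function(object) {
  cat(sprintf(paste0("SyntheticCurveSpec: K = %g, r = %g, N0 = %g; grid [%g, %g] ",
                     "by %g; noiseSd = %g, background = %g, seed = %d\n"),
              object@params@K, object@params@r, object@params@N0,
              object@tStart, object@tEnd, object@dt, object@noiseSd,
              object@background, object@seed))
})
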