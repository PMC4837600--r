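## Synthetic growth-curve generation: ground-truth logistic trajectories
## with plate-reader-like acquisition (regular grid, constant media
## background, additive Gaussian reading noise).

#' Construct a SyntheticCurveSpec
#'
#' Defaults emulate a typical bacterial OD600 plate run: readings every
#' 10 minutes (`dt = 1/6` h) for 24 hours, media background 0.09
#' absorbance units, reading noise 0.005 (additive Gaussian), and a
#' culture started from a heavy dilution (`N0 = 0.001`) growing at
#' 1 per hour to a carrying capacity of 0.5.
#'
#' @param K,r,N0 true logistic parameters.
#' @param tStart,tEnd sampling window (default 0 to 24 h).
#' @param dt sampling interval (default 1/6, i.e. 10-minute readings in
#'   hours).
#' @param noiseSd additive Gaussian noise standard deviation (default
#'   0.005, typical OD noise).
#' @param background constant additive media offset (default 0.09).
#' @param seed integer seed for the noise generator.
#' @return A [SyntheticCurveSpec-class].
#' @examples
#' syntheticCurveSpec(K = 0.7, r = 0.9, N0 = 0.005, seed = 42)
#' @export
syntheticCurveSpec <- function(K = 0.5, r = 1, N0 = 0.001,
                               tStart = 0, tEnd = 24, dt = 1 / 6,
                               noiseSd = 0.005, background = 0.09,
                               seed = 1L) {
  for (v in list(tStart, tEnd, dt, noiseSd, background, seed))
    checkFiniteNumeric(v, "spec field")
  if (dt <= 0) stopWithClass("invalidInput", "dt must be > 0")
  if (tEnd <= tStart) stopWithClass("invalidInput", "tEnd must exceed tStart")
  if (noiseSd < 0) stopWithClass("invalidInput", "noiseSd must be >= 0")
  if (background < 0) stopWithClass("invalidInput", "background must be >= 0")
  new("SyntheticCurveSpec", params = logisticParameters(K, r, N0),
      tStart = tStart, tEnd = tEnd, dt = dt, noiseSd = noiseSd,
      background = background, seed = as.integer(seed))
}

## Evaluate expr under a fixed seed without disturbing the caller's RNG
## stream.
withLocalSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hadSeed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

specGrid <- function(spec) {
  seq(spec@tStart, spec@tEnd, by = spec@dt)
}

#' Generate one synthetic growth curve
#'
#' Samples the true logistic trajectory on the spec's regular time grid
#' and adds the constant background offset plus seeded Gaussian reading
#' noise: raw_i = N(t_i) + background + eps_i with eps_i ~
#' Normal(0, noiseSd^2). Deterministic given the spec's seed; the
#' caller's RNG stream is left untouched. Negative noisy readings are
#' kept (truncation would bias the noise model); downstream min-value
#' correction handles them.
#'
#' @param spec a [SyntheticCurveSpec-class].
#' @param wellId label for the generated sample (default "synthetic").
#' @return A [GrowthSample-class] with raw readings only.
#' @export
generateCurve <- function(spec, wellId = "synthetic") {
  if (!is(spec, "SyntheticCurveSpec"))
    stopWithClass("invalidInput", "spec must be a SyntheticCurveSpec")
  validObject(spec)
  t <- specGrid(spec)
  truth <- logisticValue(spec@params, t)
  noise <- if (spec@noiseSd > 0)
    withLocalSeed(spec@seed, stats::rnorm(length(t), 0, spec@noiseSd))
  else rep(0, length(t))
  growthSample(t, truth + spec@background + noise, wellId = wellId)
}

#' Derive per-well specs for a whole synthetic plate
#'
#' Builds a named list of [SyntheticCurveSpec-class] sharing one
#' acquisition grid, with per-well seeds split deterministically from a
#' master seed by `seed_i = (masterSeed + i * 10007) mod (2^31 - 1)`
#' (i = 1..nWells), so each well gets an independent, reproducible noise
#' realization. Wells are labelled in plate-reader order A1..H12 for up
#' to 96 wells (row-major), `W<i>` beyond that.
#'
#' @param nWells number of wells (default 96).
#' @param masterSeed master seed the per-well seeds are split from.
#' @param ... passed to [syntheticCurveSpec()] (everything but `seed`).
#' @return Named list of specs.
#' @export
plateSpecs <- function(nWells = 96L, masterSeed = 1L, ...) {
  if (!is.numeric(nWells) || nWells < 1L)
    stopWithClass("invalidInput", "nWells must be a positive integer")
  nWells <- as.integer(nWells)
  labels <- if (nWells <= 96L)
    paste0(rep(LETTERS[1:8], each = 12L), rep(1:12, times = 8L))[seq_len(nWells)]
  else sprintf("W%d", seq_len(nWells))
  seeds <- (as.numeric(masterSeed) + seq_len(nWells) * 10007) %% (2^31 - 1)
  specs <- lapply(seeds, function(s) syntheticCurveSpec(..., seed = as.integer(s)))
  names(specs) <- labels
  specs
}

#' Generate a synthetic plate
#'
#' Assembles [generateCurve()] outputs for a named list of specs into a
#' [PlateTable-class]. All specs must share the same sampling grid.
#'
#' @param specs named list of [SyntheticCurveSpec-class] (e.g. from
#'   [plateSpecs()]).
#' @param blankLabel optional blank-well designation for the resulting
#'   plate.
#' @return A [PlateTable-class].
#' @examples
#' plate <- generatePlate(plateSpecs(nWells = 6, masterSeed = 11))
#' plate
#' @export
generatePlate <- function(specs, blankLabel = NA_character_) {
  if (!is.list(specs) || length(specs) == 0L ||
      !all(vapply(specs, is, logical(1), "SyntheticCurveSpec")))
    stopWithClass("invalidInput",
                  "specs must be a non-empty named list of SyntheticCurveSpec")
  if (is.null(names(specs)) || any(names(specs) == "") ||
      anyDuplicated(names(specs)))
    stopWithClass("invalidInput", "specs must carry unique well names")
  grids <- lapply(specs, specGrid)
  ref <- grids[[1L]]
  same <- vapply(grids, function(g)
    length(g) == length(ref) && all(g == ref), logical(1))
  if (!all(same))
    stopWithClass("invalidInput",
                  "all specs must share the same sampling grid (well '%s' differs)",
                  names(specs)[!same][1L])
  readings <- vapply(names(specs),
                     function(w) rawReadings(generateCurve(specs[[w]], wellId = w)),
                     numeric(length(ref)))
  readings <- matrix(readings, nrow = length(ref),
                     dimnames = list(NULL, names(specs)))
  plateTable(ref, readings, blankLabel = blankLabel)
}
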