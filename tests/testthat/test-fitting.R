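test_that("starting guess is sane and leads the fit to the truth", {
  s <- noiselessSample(K = 1, r = 1, N0 = 0.01)
  g <- initialGuess(sampleTimes(s), rawReadings(s))
  expect_equal(carryingCapacity(g), max(rawReadings(s)))
  expect_gt(growthRate(g), 0)
  expect_gt(initialPopulation(g), 0)
  fit <- summarizeGrowth(s, correction = "none")
  expect_true(converged(fit))
  expect_lt(relErr(carryingCapacity(fittedParameters(fit)), 1), 1e-6)
  # monotone ramp: K0 is the max, r0 finite positive
  ramp <- initialGuess(seq(0, 1, length.out = 11), seq(0, 1, length.out = 11))
  expect_equal(carryingCapacity(ramp), 1)
  expect_true(is.finite(growthRate(ramp)) && growthRate(ramp) > 0)
  expect_error(initialGuess(0:9, rep(0, 10)), class = "degenerateSample")
})

test_that("noiseless curves are recovered essentially exactly", {
  s <- noiselessSample(K = 0.7, r = 0.9, N0 = 0.005)
  fit <- summarizeGrowth(s, correction = "none")
  expect_true(converged(fit))
  p <- fittedParameters(fit)
  expect_lt(relErr(carryingCapacity(p), 0.7), 1e-6)
  expect_lt(relErr(growthRate(p), 0.9), 1e-6)
  expect_lt(relErr(initialPopulation(p), 0.005), 1e-6)
  expect_lt(fit@sigma, 1e-8)
  expect_identical(fit@dof, length(sampleTimes(s)) - 3)
  expect_equal(fit@tDoubling, log(2) / growthRate(p))
  expect_equal(fit@tMid, log((carryingCapacity(p) - initialPopulation(p)) /
                               initialPopulation(p)) / growthRate(p))
})

test_that("degenerate wells return non-converged results, not exceptions", {
  flat <- summarizeGrowth(growthSample(0:9, rep(0.25, 10)))
  expect_false(converged(flat))
  expect_match(flat@note, "constant")
  dec <- summarizeGrowth(growthSample(0:9, seq(0.9, 0.1, length.out = 10)),
                         correction = "none")
  expect_false(converged(dec))
  expect_match(dec@note, "decreasing")
  # malformed input is an error, not a result
  expect_error(fitLogistic(growthSample(0:9, rep(0.1, 10))),
               class = "invalidInput")   # no correction applied
  expect_error(summarizeGrowth(growthSample(0:3, c(0.1, 0.2, 0.3, 0.4))),
               class = "invalidInput")   # fewer than 5 points
})

test_that("returned parameters do not worsen the starting guess", {
  set.seed(11)
  for (i in 1:5) {
    spec <- syntheticCurveSpec(K = runif(1, 0.3, 1), r = runif(1, 0.5, 2),
                               N0 = runif(1, 1e-3, 0.02),
                               noiseSd = 0.01, background = 0.05,
                               seed = 100 + i)
    s <- subtractMinBackground(generateCurve(spec))
    y <- correctedReadings(s); tt <- sampleTimes(s)
    fit <- fitLogistic(s)
    expect_true(converged(fit))
    rss <- function(p) sum((y - logisticValue(p, tt))^2)
    expect_lte(rss(fittedParameters(fit)), rss(initialGuess(tt, y)))
  }
})

test_that("metrics inherit the input time unit", {
  hours <- noiselessSample(K = 0.6, r = 1.2, N0 = 0.006)
  minutes <- growthSample(sampleTimes(hours) * 60, rawReadings(hours))
  fh <- summarizeGrowth(hours, correction = "none")
  fm <- summarizeGrowth(minutes, correction = "none")
  expect_equal(growthRate(fittedParameters(fh)) /
                 growthRate(fittedParameters(fm)), 60, tolerance = 1e-6)
  expect_equal(carryingCapacity(fittedParameters(fh)),
               carryingCapacity(fittedParameters(fm)), tolerance = 1e-6)
  expect_equal(initialPopulation(fittedParameters(fh)),
               initialPopulation(fittedParameters(fm)), tolerance = 1e-5)
  expect_equal(fm@tDoubling, fh@tDoubling * 60, tolerance = 1e-6)
})

test_that("residual sigma tracks the injected noise level down to zero", {
  sigmas <- vapply(c(0.02, 0.01, 0.005, 0), function(ns) {
    spec <- syntheticCurveSpec(K = 0.7, r = 0.9, N0 = 0.005,
                               noiseSd = ns, background = 0, seed = 77)
    fit <- summarizeGrowth(generateCurve(spec), correction = "none")
    expect_true(converged(fit))
    fit@sigma
  }, numeric(1))
  expect_true(all(diff(sigmas) < 0))
  expect_lt(sigmas[4], 1e-8)
})

test_that("standard errors are finite and positive for noisy fits", {
  spec <- syntheticCurveSpec(K = 0.7, r = 0.9, N0 = 0.005,
                             noiseSd = 0.005, background = 0.09, seed = 5)
  fit <- summarizeGrowth(generateCurve(spec))
  expect_true(converged(fit))
  expect_true(all(is.finite(fit@stderr)) && all(fit@stderr > 0))
  # the true values sit within a few standard errors of the estimates
  p <- fittedParameters(fit)
  expect_lt(abs(growthRate(p) - 0.9), 6 * fit@stderr[["r"]])
})

test_that("summarizeGrowth equals the manual correction+fit composition", {
  spec <- syntheticCurveSpec(K = 0.5, r = 1.1, N0 = 0.008, seed = 7)
  s <- generateCurve(spec)
  auto <- summarizeGrowth(s)
  manual <- fitLogistic(subtractMinBackground(s))
  expect_equal(metricsRow(auto), metricsRow(manual))
})

test_that("the AUC window end restricts both AUC flavours", {
  s <- noiselessSample(K = 0.8, r = 1, N0 = 0.01)
  half <- max(sampleTimes(s)) / 2
  fit <- summarizeGrowth(s, correction = "none", tAUCEnd = half)
  expect_true(converged(fit))
  expect_equal(fit@aucLogistic,
               logisticAUC(fittedParameters(fit), sampleTimes(s)[1], half))
  expect_equal(fit@aucEmpirical,
               empiricalAUC(sampleTimes(s), rawReadings(s), tEnd = half))
  expect_error(summarizeGrowth(s, tAUCEnd = 100), class = "invalidInterval")
})

test_that("background-offset wells recover the truth through the pipeline", {
  spec <- syntheticCurveSpec(K = 0.65, r = 1.3, N0 = 0.003,
                             noiseSd = 0.003, background = 0.09, seed = 21)
  fit <- summarizeGrowth(generateCurve(spec))
  expect_true(converged(fit))
  expect_lt(relErr(carryingCapacity(fittedParameters(fit)), 0.65), 0.05)
  expect_lt(relErr(growthRate(fittedParameters(fit)), 1.3), 0.1)
})
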