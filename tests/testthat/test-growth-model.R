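test_that("logistic curve collapses correctly at its fixed points", {
  # at capacity (K = N0) the population never moves
  p <- logisticParameters(K = 1, r = 2.7, N0 = 1)
  expect_equal(logisticValue(p, c(-3, 0, 1, 50)), rep(1, 4))
  # t = 0 returns N0 exactly
  p2 <- logisticParameters(K = 0.8, r = 1.3, N0 = 0.017)
  expect_identical(logisticValue(p2, 0), 0.017)
})

test_that("logistic trajectory matches an independent ODE integration", {
  skip_if_not_installed("deSolve")
  p <- logisticParameters(K = 0.5, r = 0.5, N0 = 0.01)
  ode <- deSolve::ode(
    y = c(N = 0.01), times = c(0, 10),
    func = function(t, y, parms) list(parms$r * y * (1 - y / parms$K)),
    parms = list(r = 0.5, K = 0.5),
    method = "lsoda", rtol = 1e-12, atol = 1e-14
  )
  expect_equal(logisticValue(p, 10), unname(ode[2, "N"]), tolerance = 1e-9)
})

test_that("logistic curve is monotone, bounded, and inflects at K/2", {
  p <- logisticParameters(K = 0.9, r = 1.4, N0 = 0.003)
  tt <- seq(-5, 30, by = 0.05)
  v <- logisticValue(p, tt)
  expect_true(all(diff(v) >= 0))
  # strictly increasing wherever the increment is representable in doubles
  # (beyond t ~ 25 the curve sits within machine epsilon of K)
  expect_true(all(diff(logisticValue(p, seq(-5, 18, by = 0.05))) > 0))
  expect_true(all(v > 0 & v <= p@K))
  expect_equal(logisticValue(p, 1e4), 0.9, tolerance = 1e-12)
  tMid <- inflectionTime(p)
  expect_lt(abs(logisticValue(p, tMid) - p@K / 2), 1e-9 * p@K)
})

test_that("logisticValue rejects non-finite inputs", {
  p <- logisticParameters(1, 1, 0.1)
  expect_error(logisticValue(p, NaN), class = "invalidInput")
  expect_error(logisticValue(p, Inf), class = "invalidInput")
  expect_error(logisticValue("nope", 1), class = "invalidInput")
})

test_that("doubling time follows ln2/r and its error paths are distinct", {
  expect_equal(doublingTime(log(2)), 1)
  expect_equal(doublingTime(2 * log(2)), 0.5)
  # cross-check ln2/0.3 by bisection on the curve itself in the K >> N0
  # regime, where growth is effectively unrestricted
  p <- logisticParameters(K = 1e9, r = 0.3, N0 = 1)
  tDouble <- uniroot(function(t) logisticValue(p, t) - 2, c(0.1, 10),
                     tol = 1e-12)$root
  expect_equal(doublingTime(0.3), tDouble, tolerance = 1e-6)
  expect_error(doublingTime(0), class = "nonpositiveGrowthRate")
  expect_error(doublingTime(-1), class = "nonpositiveGrowthRate")
  expect_error(doublingTime(NA_real_), class = "nonFiniteGrowthRate")
  expect_error(doublingTime(Inf), class = "nonFiniteGrowthRate")
})

test_that("doubling time is an exact reciprocal relation in r", {
  rs <- exp(runif(50, log(0.01), log(15)))
  expect_equal(doublingTime(rs) * rs, rep(log(2), 50))
  expect_identical(cor(rs, doublingTime(rs), method = "spearman"), -1)
})

test_that("closed-form logistic AUC agrees with adaptive quadrature", {
  p <- logisticParameters(K = 0.8, r = 1.2, N0 = 0.02)
  quad <- integrate(function(x) logisticValue(p, x), 0, 24,
                    rel.tol = 1e-12, abs.tol = 0)$value
  expect_equal(logisticAUC(p, 0, 24), quad, tolerance = 1e-8)
  # nonzero start point
  quad2 <- integrate(function(x) logisticValue(p, x), 3, 17,
                     rel.tol = 1e-12, abs.tol = 0)$value
  expect_equal(logisticAUC(p, 3, 17), quad2, tolerance = 1e-8)
})

test_that("logistic AUC handles degenerate and extreme regimes", {
  p <- logisticParameters(K = 0.8, r = 1.2, N0 = 0.02)
  expect_identical(logisticAUC(p, 5, 5), 0)
  # constant integrand when K = N0
  pc <- logisticParameters(K = 0.3, r = 4, N0 = 0.3)
  expect_equal(logisticAUC(pc, 0, 7), 0.3 * 7)
  # r = 0: flat at N0
  p0 <- logisticParameters(K = 1, r = 0, N0 = 0.2)
  expect_equal(logisticAUC(p0, 0, 10), 2)
  # r*t far beyond exp() overflow: e.g. per-minute rates over long runs;
  # past saturation the area grows by ~K per unit time
  pBig <- logisticParameters(K = 1, r = 5, N0 = 0.01)
  a1 <- logisticAUC(pBig, 0, 400)
  a2 <- logisticAUC(pBig, 0, 401)
  expect_true(is.finite(a1))
  expect_equal(a2 - a1, 1, tolerance = 1e-10)
  # declining curve (N0 > K) still integrates correctly
  pd <- logisticParameters(K = 0.1, r = 0.8, N0 = 0.4)
  quadD <- integrate(function(x) logisticValue(pd, x), 0, 12,
                     rel.tol = 1e-12, abs.tol = 0)$value
  expect_equal(logisticAUC(pd, 0, 12), quadD, tolerance = 1e-8)
  expect_error(logisticAUC(p, 2, 1), class = "invalidInterval")
})

test_that("trapezoid AUC matches an independent pairwise sum", {
  expect_equal(empiricalAUC(c(0, 1), c(1, 1)), 1)
  # trapezoid rule is exact for constants regardless of sampling
  tt <- sort(runif(15, 0, 8))
  expect_equal(empiricalAUC(tt, rep(2.5, 15)), 2.5 * (max(tt) - min(tt)))
  # 20 random points vs a loop-free re-derivation and pracma's trapz
  set.seed(42)
  t20 <- sort(runif(20, 0, 24))
  v20 <- runif(20, 0, 1)
  brute <- sum(vapply(seq_len(19), function(i)
    0.5 * (v20[i] + v20[i + 1]) * (t20[i + 1] - t20[i]), numeric(1)))
  expect_equal(empiricalAUC(t20, v20), brute)
  skip_if_not_installed("pracma")
  expect_equal(empiricalAUC(t20, v20), pracma::trapz(t20, v20))
})

test_that("trapezoid AUC truncates the final panel at tEnd by interpolation", {
  tt <- c(0, 1, 2)
  vv <- c(0, 1, 2)   # y = t, area over [0, 1.5] is 1.5^2/2
  expect_equal(empiricalAUC(tt, vv, tEnd = 1.5), 1.125)
  # tEnd inside the first interval
  expect_equal(empiricalAUC(tt, vv, tEnd = 0.5), 0.125)
})

test_that("trapezoid AUC validates its inputs", {
  expect_error(empiricalAUC(c(0, 1, 1), c(1, 2, 3)), class = "invalidInput")
  expect_error(empiricalAUC(c(2, 1, 0), c(1, 2, 3)), class = "invalidInput")
  expect_error(empiricalAUC(c(0, 1), c(1, 2), tEnd = 5),
               class = "invalidInterval")
  expect_error(empiricalAUC(c(0, 1), c(1, 2), tEnd = 0),
               class = "insufficientData")
  expect_error(empiricalAUC(0, 1), class = "insufficientData")
})
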