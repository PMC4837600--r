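---
title: "Fitting logistic growth curves to plate-reader data"
author: "microgrowth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting logistic growth curves to plate-reader data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microgrowth)
```

## The model

A batch microbial culture in fresh medium grows roughly exponentially
until nutrients or space become limiting, then decelerates and plateaus.
The simplest model capturing that shape is the logistic equation,

$$ N(t) = \frac{K}{1 + \frac{K - N_0}{N_0}\, e^{-r t}}, $$

the solution of $dN/dt = r N (1 - N/K)$. Its three parameters each answer
a concrete biological question. $K$, the carrying capacity, is the
maximum population the environment sustains — the curve's plateau. $r$,
the intrinsic growth rate, is the per-capita rate the population would
sustain with no density limitation; the curve behaves like
$N_0 e^{rt}$ while $N \ll K$. $N_0$ is the population at the first
reading. The curve inflects at $t_{mid} = \ln((K-N_0)/N_0)/r$, where
$N = K/2$, and the fastest doubling time — attained far from capacity —
is $t_{dt} = \ln 2 / r$. Because $t_{dt}$ is a strictly decreasing
transform of $r$, the Spearman correlation between fitted growth rates
and doubling times is $-1$ by construction, a useful end-to-end sanity
check on any batch of fits.

The package imposes no unit system: every output inherits the unit of the
input time vector (hours in, per-hour and hours out), and readings keep
whatever proxy the instrument reports (typically OD600 absorbance).

### Area under the curve

Two AUC flavours summarize growth over a window $[t_1, t_2]$. The
*logistic* AUC integrates the fitted model in closed form using the
antiderivative

$$ \int N(\tau)\, d\tau = \frac{K}{r} \ln\!\left(e^{r\tau} + A\right),
\qquad A = \frac{K - N_0}{N_0}, $$

evaluated at the endpoints. The *empirical* AUC is the trapezoid-rule
area under the observed corrected readings — a non-parametric companion
that does not trust the model. On a well-behaved logistic well the two
agree closely; a large gap flags readings the model does not describe
(diauxie, death phase, artifacts).

Numerically, $e^{r\tau}$ overflows for quite ordinary inputs (per-minute
rates over long runs), so the implementation evaluates
$\ln(e^{x} + A) = \max(x, \ln A) + \log(1 + e^{-|x - \ln A|})$
(log-sum-exp). The degenerate cases $K = N_0$ and $r = 0$ (constant
curve) integrate exactly as $N_0 (t_2 - t_1)$. Correctness of the closed
form is asserted against adaptive quadrature (relative $10^{-8}$, in
practice $\sim 10^{-10}$) across randomized parameter sweeps in the test
suite and the acceptance script. When the window end falls between two
sample points, the empirical AUC truncates the final trapezoid by linear
interpolation — the natural extension of the trapezoid geometry; the
convention is stated here because reasonable alternatives (dropping or
keeping the whole panel) exist.

## Background correction

Raw absorbance includes the media's contribution. Two corrections are
offered, as mutually exclusive modes. The default, `min_value`, subtracts
each well's own minimum reading, requiring no extra wells and making
every fitted parameter invariant to any constant offset; it is idempotent
and never produces negative values. `blank_series` subtracts a designated
media-only well point by point, which can also remove slow shared drift
(e.g. evaporation); negative corrected values are *kept* and flagged, not
clipped — clipping would bias the numerous, information-poor early
points, while the fit's positivity bound on $N_0$ already handles them.
With a noisy blank, min-value correction is usually the better default,
which is also why it is the package's.

Note one small, deliberate side effect of min-value correction under
noise: subtracting the observed minimum of $n$ noisy readings shifts the
whole series up by roughly the expected minimum of $n$ noise draws
(≈ 2.5 standard deviations at $n = 145$), which biases $\hat K$ upward by
a fraction of a percent at typical OD noise. This is inherent to the
correction, not the fit.

## Fitting

Estimation is nonlinear least squares: minimize
$\sum_i (y_i - N(t_i; K, r, N_0))^2$ over the corrected readings, by the
Levenberg–Marquardt algorithm as implemented in `minpack.lm`, with box
constraints.

**Starting values.** $K_0 = \max y$; $N_{0,0} = \max(y_1, \varepsilon)$
with $\varepsilon = 10^{-6} \max y$ guarding the zeros min-subtraction
creates; $r_0$ is the slope of a least-squares line through
$\ln(y + \varepsilon)$ versus $t$ over the points between 10 % and 50 %
of the maximum — the near-exponential phase — falling back to 1 per time
unit when fewer than 3 such points exist.

**Constraints.** $r \in (0, r_{\max}]$ with $r_{\max} = 20$ per time unit
by default (configurable): a cap that excludes step-function artifacts
while sitting far above any plausible microbial rate at sane units.
$N_0 \in [\varepsilon, \max y]$. $K$ starts bounded by $10 \max y$; if a
*converged* fit lands on that ceiling — the signature of a curve still
far from saturation at the last reading, where the information about $K$
lives in the curvature rather than the maximum — the ceiling is expanded
a hundredfold and the fit restarted from the constrained solution, up to
four times ($10^9 \max y$ cap). A fixed ceiling would silently clip $K$
for slow growers; unbounded $K$ diverges on flat wells. The adaptive
ceiling keeps both behaviours: well-behaved data reach the same optimum
an unconstrained fit would, and pathological wells stay finite.

**Tolerances.** Relative cost tolerance and parameter tolerance of
$10^{-10}$, at most 1000 iterations. On noiseless synthetic curves these
recover parameters to relative $10^{-13}$; they are deliberately tight
because the fits are cheap (a 145-point well fits in tens of
milliseconds).

**Diagnostics.** `sigma` $= \sqrt{RSS / (n - 3)}$ is the residual
standard error; standard errors come from the usual Jacobian-based
covariance $\hat\sigma^2 (J^\top J)^{-1}$ and are reported as `NA` — not
zero — when the Jacobian is rank-deficient. Degenerate wells (constant,
all-zero or monotonically decreasing signal) and optimizer failures
return a result object with `converged = FALSE` and an explanatory note
rather than throwing: in a plate of 96 wells, one contaminated or empty
well must not abort the run. A fit with $\hat N_0 \ge \hat K$ (a
declining or flat well the optimizer could still describe) is returned
but flagged in the note.

## The synthetic generator

`syntheticCurveSpec()` / `generateCurve()` / `generatePlate()` emulate a
typical plate run: a regular sampling grid (default 10-minute readings
for 24 h, i.e. 145 points — the standard overnight protocol), a constant
media background (default 0.09 absorbance units), and additive Gaussian
reading noise (default sd 0.005, typical for OD600). Default ground truth
is a culture at heavy dilution ($N_0 = 0.001$) growing at $r = 1$/h to
$K = 0.5$. Per-well seeds are split from a master seed as
$s_i = (s + 10007\, i) \bmod (2^{31}-1)$, so plates are reproducible well
by well and wells get independent noise realizations; generation never
touches the caller's RNG stream.

The generator is deliberately simpler than real data: noise is additive,
homoscedastic and Gaussian (real OD noise is mildly heteroscedastic),
the background is constant (no evaporation drift), and the trajectories
are exactly logistic — no lag phase, diauxic shifts or death phase.
Passing tests therefore demonstrate that the estimator recovers
parameters *when the model holds and noise is well-behaved*; they say
nothing about model misspecification on real curves, for which the
empirical-vs-logistic AUC gap and `sigma` are the per-well warning
lights.

Negative noisy readings are kept, not truncated: truncation would distort
exactly the noise model the recovery tests assume.

## Problem sizes and expectations

The validation suite works at desk scale: plates of 6–96 wells at 145
time points, parameter sweeps of 27 noiseless grid points
($K \in [0.1, 2]$, $r \in [0.1, 3]$/h, $N_0/K \in [10^{-4}, 0.05]$),
1000-draw quadrature sweeps, and 100-replicate noise studies. Under
those conditions: noiseless recovery is exact to $\sim 10^{-13}$
relative; at noise sd 0.005 the growth rate of a ($K = 0.7$,
$r = 0.9$/h, $N_0 = 0.005$) well is recovered with median relative error
under 2 % (observed ≈ 1 %); across a default 96-well plate, worst-case
errors stay within 6 % for $K$ and 12 % for $r$, while $N_0$ — the
weakly identified parameter at heavy dilution, where the signal sits
below the noise floor for the first hours — can be off by over 50 % and
is better read with its standard error alongside.

## Limitations

- One model: strains with lag phases, diauxie or death phases need
  richer growth models (Gompertz, Baranyi, Richards), which are out of
  scope; on such wells inspect `sigma` and the AUC gap.
- $N_0$ from heavily diluted inocula is intrinsically poorly determined
  by OD data; treat $\hat N_0$ as order-of-magnitude.
- No smoothing, outlier removal or evaporation correction is applied;
  the correction modes are strictly the two described above.
- Confidence intervals are Wald-type (from the Jacobian); no bootstrap.
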