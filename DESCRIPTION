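Package: microgrowth
Title: Interpretable Metrics from Microbial Growth Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the standard logistic population-growth equation to
    plate-reader absorbance (e.g. OD600) time series by bounded
    Levenberg-Marquardt nonlinear least squares and reports interpretable
    population-level metrics: carrying capacity, intrinsic growth rate,
    initial population size, fastest doubling time, and the area under the
    curve both in closed form from the fitted model and empirically by the
    trapezoid rule. Works on single wells or whole plates read from wide
    CSV/TSV tables, includes background-correction options (per-well
    minimum or blank-well series), and ships a synthetic growth-curve
    generator for validation and demos, plus a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    optparse
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'growth-model.R'
    'preprocessing.R'
    'fitting.R'
    'plate-io.R'
    'synthetic-data.R'
    'cli.R'
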