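Package: ahmnull
Title: Null-Model Benchmarks for Adaptive Harvest Management Forecasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forecasting pipeline for benchmarking mechanistic adaptive
    harvest management (AHM) population models against ecological null
    models. Implements the age- and sex-structured AHM balance equation
    with additive/compensatory harvest-mortality and weak/strong
    density-dependent reproduction submodels, two ecological null models
    (stochastic population persistence and a wetland-driven growth model
    fit by conjugate Bayesian regression), expanding-window one-step-ahead
    forecast evaluation with normalized RMSE and normalized mean signed
    difference skill scores, iterative Bayesian model-weight updating,
    and a synthetic-data generator for abundance, wetland, and
    harvest-rate series.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
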