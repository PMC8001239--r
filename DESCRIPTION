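Package: spillnet
Title: Dynamic Connectedness Networks and Robust Regression for
    Disease-Specific Healthcare Expenditure Spillovers
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measures spillovers among disease-specific healthcare
    expenditure time series with a time-varying-parameter vector
    autoregression (Kalman filter with forgetting factors) and the
    generalized forecast-error variance decomposition, producing total,
    directional, net total and net pairwise connectedness indices and
    transmitter/receiver network classifications.  The monthly-aggregated
    indices are then regressed on demographic, macroeconomic and
    healthcare-utilization covariates by MM-estimation robust least
    squares with OLS influence diagnostics (RStudent, DFFITS, CovRatio).
    Includes preprocessing tools (per-capita deflation, Hodrick-Prescott
    trend/cycle decomposition, Phillips-Perron unit-root screening,
    weekly-to-monthly aggregation), a seeded synthetic-data generator
    with known ground truth, and an end-to-end pipeline with a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
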