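Package: gtwr
Title: Geographically and Temporally Weighted Regression for City-Level
    Demographic Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing spatiotemporal heterogeneity in city-level
    demographic panels such as birth rates. Implements geographically and
    temporally weighted regression (GTWR) with spatiotemporal kernel
    weights, leave-one-out cross-validated bandwidth calibration, local
    weighted least squares, and fit diagnostics (effective parameters,
    adjusted R-squared, AICc), together with spatial autocorrelation
    statistics (global and local Moran's I with permutation inference,
    Getis-Ord Gi* hot-spot detection), spatial weights construction, a
    synthetic panel generator with known space-time-varying coefficient
    surfaces for parameter-recovery testing, and reporting utilities for
    coefficient summaries, phase comparisons, temporal trends, and
    coefficient maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
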