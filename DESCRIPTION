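Package: forestdyn
Title: Forest Census Dynamics, Allometric Biomass, and Functional Trait Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing repeated forest-census data from permanent
    plots: growth-form-specific allometric aboveground biomass estimation
    (angiosperm, Araucaria, palm, tree fern) with tiered wood-density
    resolution, threshold-based functional-group classification,
    community-weighted trait means and functional dispersion, percentile
    bootstrap inference on plot-level net-change rates of stand structure
    and trait composition, and a trend battery for annual climate series
    (linear trends, LOESS smoothing, Durbin-Watson and autocorrelation
    diagnostics, opposite-tails Grubbs outlier test, breakpoint period
    comparison). Includes an individual-based synthetic forest-census and
    climate generator with a ground-truth event log, so every analysis
    stage can be validated against known dynamics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    withr,
    jsonlite
Config/testthat/edition: 3
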