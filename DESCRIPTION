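Package: mmrcal
Title: Calibrated District-Level Maternal Mortality Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates district-level maternal mortality ratios (MMR) from
    facility-reported counts and calibrates them against a gold-standard
    reference registration system. Implements raw MMR/IMR computation,
    per-state calibration factors with an infant-mortality proxy fallback,
    population-weighted state aggregation, SDG-3.1 classification and
    registration-completeness checks; a composite health-infrastructure
    index built from HDI-style min-max dimension indices with an
    urban-share adjustment; queen-contiguity spatial weights with global
    and local Moran's I (LISA) under conditional-permutation inference,
    including the bivariate form; and log-linear OLS correlate models with
    heteroskedasticity-robust standard errors and a pairwise-correlation
    collinearity screen. A synthetic multi-state district generator with
    known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    sandwich,
    lmtest
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
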