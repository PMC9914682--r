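Package: nirnoise
Title: Multivariate Measurement-Error Analysis for Replicated NIR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Characterizes the structure of measurement error in replicated
    reflectance spectra from miniaturized near-infrared (NIR) sensors.
    Estimates error covariance and correlation matrices from replicate
    deviations, decomposes them by bilinear (PCA) modeling to separate
    correlated from independent noise, computes the K redundancy index and
    its rank-constrained imbedded-correlation floor, screens outlying
    replicates with Hotelling T-squared and Q residual statistics, and
    reports per-wavelength reproducibility descriptives (standard deviation,
    RMS, signal-to-noise). Ships a synthetic-data generator with a
    closed-form theoretical error covariance (offset, multiplicative, shot,
    independent, session and background-timing noise components) for method
    validation, plus a pipeline driver that writes the full set of tables
    and figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
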