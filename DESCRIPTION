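Package: socgeo
Title: Geostatistical Analysis of Soil Organic Carbon Spatial Variability and Stocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for grid-survey studies of soil organic
    carbon (SOC) in arid soils: layer-wise descriptive statistics with
    normality testing and LSD mean separation, sub-area re-sampling curves of
    the coefficient of variation with power-law scaling and sample-size
    planning, empirical semivariograms with weighted-least-squares variogram
    model fitting and nugget-ratio spatial-dependence classification, ordinary
    kriging with leave-one-out cross-validation and map export, Pearson
    correlation and forward stepwise regression against soil physical
    covariates, and SOC density and stock accounting with coarse-fragment
    correction. A seeded Gaussian random-field simulator reproduces the
    statistical structure of a 500 m grid desert survey so the whole pipeline
    is testable without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    nortest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
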