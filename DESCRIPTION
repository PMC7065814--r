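Package: wheatgpc
Title: Satellite Prediction of Winter-Wheat Grain Protein Content by
    Partial Least Squares
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to estimate winter-wheat grain protein content (GPC)
    from four-band (blue, green, red, near-infrared) surface reflectance.
    Implements the empirical-line digital-number to reflectance
    calibration, ten classical multispectral vegetation indices, a
    from-scratch PLS1 (NIPALS) regression core with leave-one-out PRESS
    component selection and VIP scores, ordinary least squares and
    principal-components regression baselines, model evaluation
    (modeling/verification split, correlation screening, RMSE and
    accuracy scoring), and gridded GPC map production with class binning.
    A seeded synthetic-scene generator reproduces the statistical
    structure of field campaigns so the whole pipeline is testable
    without proprietary satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
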