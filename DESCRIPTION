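Package: coccomorph
Title: Coccolith Morphometry and Mass Estimation from Polarised-Light Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of coccolith length-thickness-mass
    relationships measured by calibrated circular-polarised-light microscopy.
    Provides a forward optical model linking calcite thickness, optical
    retardation and image grey value; a synthetic-micrograph generator with
    per-coccolith ground truth; the inverse measurement pipeline (edge-based
    segmentation, moment-ellipse morphometry, grey-to-mass calibration,
    uncertainty propagation); the k_s shape-factor mass model and its bias
    audit; and the statistical layer used to test whether coccolith length
    and thickness scale isometrically (one-way ANOVA, Tukey HSD, ordinary
    least squares with global assumption validation, influence diagnostics,
    and a resolvability rule based on measurement uncertainty).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
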