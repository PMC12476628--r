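Package: cardioquant
Title: Cardiac Function Quantification from Fluorescent Heart-Beating
    Videos, Bliss Synergy and Survival Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies larval-zebrafish cardiac function (fractional area
    change, fractional shortening, stroke volume, cardiac output, heart
    rate) from fluorescence time-lapse videos by chamber segmentation and
    rotated minimum-area-rectangle geometry; analyses drug synergy of
    rescue-type endpoints under the Bliss Independence model (rescue-effect
    normalization, additive threshold, combination index, observed-versus-
    additive test); and compares interval-recorded survival with
    Kaplan-Meier curves and the log-rank test.  A synthetic-data module
    simulates beating-heart videos, treatment cohorts and survival
    experiments with known ground truth so every stage of the pipeline is
    verifiable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    EBImage,
    survival,
    tiff,
    png,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'conditions.R'
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'segmentation.R'
    'cardiometrics.R'
    'cardioquant-package.R'
    'io.R'
    'survstats.R'
    'synergy.R'
    'synthgen.R'
    'pipeline.R'
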