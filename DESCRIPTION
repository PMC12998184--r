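Package: gutnitro
Title: Nitrite and Nitrate Degradation Kinetics of the Gut Microbiota
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying bacterial nitrite and nitrate detoxification
    in the human intestine: colorimetric (Griess-type) assay calibration with
    detection-limit censoring, correction of incubation time series for abiotic
    nitrite losses (cysteine scavenging, pH-dependent decay), substrate-depletion
    kinetics yielding specific activities in umol per g dry weight per hour,
    biomass calibration from counting-chamber and dry-weight data, whole-colon
    extrapolation of detoxification capacity, and classification of
    nitrite-dependent growth-inhibition phenotypes. A synthetic-data module
    generates growth curves, depletion courses, calibration standards and
    counting experiments with known ground truth so that every stage of the
    pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
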