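Package: phenoherb
Title: Herbarium-Based Estimation of Flowering-Phenology Responsiveness to Temperature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates species-level flowering-phenology responsiveness to
    temperature from herbarium specimen records paired with climate-division
    monthly temperatures. Aggregates station temperatures to divisions,
    computes seasonal anomalies and warming trends, screens lagged temperature
    windows, fits per-species ordinary least squares responsiveness (days per
    degree Celsius), compares plant functional groups with random-slope linear
    mixed models and likelihood-ratio tests, and profiles Pagel's lambda for
    phylogenetic signal in responsiveness by generalised least squares. A
    synthetic-data generator with known ground truth supports calibration and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    ape,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    phytools,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
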