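Package: broomrape
Title: Thermal-Time Phenology of Crenate Broomrape Parasitism on Legumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling the underground development of crenate
    broomrape (Orobanche crenata) on legume host crops as a function of
    thermal time. Accumulates growing degree days (GDD) from hourly soil
    temperature records, fits three-parameter logistic growth curves to
    log-transformed, stage-structured attachment counts by nonlinear least
    squares, segments fitted curves into lag, log and maximum phases,
    compares fitted parameters between host crops with standard-error based
    t tests and a species-by-year analysis of variance, and simulates
    complete field trials (soil temperature plus cohort-based stage
    progression) for testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
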