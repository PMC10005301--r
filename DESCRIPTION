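Package: chromlogd
Title: Chromatographic Estimation of Apparent Octanol/Water Partition
    Coefficients of Basic Compounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the apparent n-octanol/water distribution
    coefficient (logD) of ionizable basic compounds from isocratic
    reversed-phase liquid chromatography retention measured at several
    mobile-phase pH values. Retention factors are extrapolated to a fully
    aqueous mobile phase (logkw) under the linear solvent strength model
    with dual-point retention-time correction, literature logD values are
    derived from logP and pKa by Henderson-Hasselbalch ionization
    correction, and per-pH quantitative structure-retention relationship
    (QSRR) models linking logD to logkw and molecular descriptors
    (electrostatic charge n_e, hydrogen-bond acidity A and basicity B) are
    fitted by multiple linear regression with descriptor-subset selection,
    externally validated by signed relative error, and used to predict
    logD of unknown samples. A seeded synthetic-study generator produces
    complete artificial data sets with known ground truth for testing
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
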