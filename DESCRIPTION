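Package: eecalib
Title: Calibration and Validation of Accelerometer-Based Energy Expenditure Measurement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating consumer activity monitors against criterion
    and convergent references. Fits linear count-to-energy-expenditure
    calibration models, inverts them into MET-anchored intensity cut-points,
    computes energy expenditure from indirect calorimetry, cleans epoch-level
    free-living actigraphy (nonwear removal, valid-day screening, intensity
    classification), runs a full method-agreement battery (systematic-bias
    t-tests, Bland-Altman limits of agreement, Pearson correlation, two-way
    random absolute-agreement ICC, intensity-level ANOVA with
    Bonferroni-corrected pairwise comparisons), and builds intensity-annotated
    space-time trajectories from GPS fix logs. Includes synthetic-data
    generators that emulate treadmill calibration protocols, gas-exchange
    kinetics, free-living days with nonwear and phone-noncarry blocks, and
    GPS tracks with accuracy-dependent noise, so every stage is testable
    without access to raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
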