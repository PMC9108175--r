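Package: wristcutpoints
Title: Validation of Youth Wrist Accelerometer Intensity Cut-Points Against
    Calorimetry-Style Ground Truth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a laboratory cohort of children and adolescents
    performing structured activity trials while wearing wrist accelerometers
    and a portable calorimeter, and evaluates published youth-specific
    intensity cut-points against the measured energy expenditure. Provides
    the full processing chain: raw-signal autocalibration, ENMO and activity
    count vector-magnitude metrics, analysis-window extraction with
    steady-state verification, Youth MET computation from Schofield resting
    energy expenditure, seven built-in wrist cut-point classifiers, and
    agreement analysis via weighted Cohen's kappa, confusion matrices,
    per-class accuracy and per-activity misclassification direction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
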