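Package: dipstickr
Title: Semi-Quantitative Urine Dipstick Reading from Smartphone Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reads colorimetric urine test strips from smartphone
    photographs. Reagent-pad colors are reduced to mean RGB triplets,
    converted between RGB and HSV color spaces, and mapped to analyte
    concentrations through per-channel linear or log-linear calibration
    curves fitted by ordinary least squares; the channel with the most
    linear response (highest r-squared) is selected per analyte. Ships a
    built-in seven-analyte panel (pH, glucose, ketones, hemoglobin,
    bilirubin, protein, nitrites), Bland-Altman agreement analysis
    against a reference urine analyzer, a nearest-exemplar reference
    store with confusion-matrix accuracy tracking for reproducible
    categorical readouts, and a seeded synthetic-data generator that
    emulates dilution series of artificial urine.
License: MIT
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
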