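Package: glucofuzz
Title: Fuzzy-Logic-Reinforced Non-Invasive Glucose Measurement Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis chain for near-infrared non-invasive glucose
    biosensing reinforced with fuzzy logic. Provides Clarke Error Grid
    (CEG) zone classification with a continuous zone-position (severity)
    score, a from-scratch two-input Mamdani fuzzy inference system with
    triangular membership functions and centroid defuzzification that
    converts sensor voltage and CEG position into a predicted glucose
    error tolerance, ordinary-least-squares voltage-to-glucose
    calibration, and a physics-based sensor simulator (Bouguer-Lambert
    attenuation, transimpedance/gain circuit model) that generates
    study-shaped synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
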