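Package: fallvibe
Title: Fall Detection from Floor Vibration with Multi-Feature
    Semi-Supervised Support Vector Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects human falls from structural floor-vibration
    measurements. Extracts three feature views from multi-channel
    accelerometer event records (per-sensor peak value, per-sensor signal
    energy, and pairwise sensor correlation coefficients), trains one
    radial-basis-function support vector machine per view, refines the
    three classifiers cooperatively with tri-training on unlabeled events
    (margin-proximity pseudo-labeling with label-flip removal), and fuses
    them by majority vote. Ships a four-stage biomechanical model of the
    vertical floor force produced by an unconscious backward fall (a
    three-degree-of-freedom damped body model for the impact stage), a
    modal plate simulator that turns force profiles for six activity
    types into seeded synthetic multi-sensor acceleration datasets, and
    confusion-matrix evaluation with per-activity false-alarm breakdown.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    pracma,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    arrow,
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
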