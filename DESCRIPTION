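Package: harvalue
Title: Reinforcement-Learning Data Valuation for Wearable-Sensor Activity
    Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the value of individual training windows in
    multivariate wearable-sensor (IMU) human activity recognition datasets.
    A data value estimator -- a 1D convolutional backbone followed by a
    transformer encoder, conditioned on the label and on marginal
    information from a validation-pretrained predictor -- outputs a
    per-sample selection probability, trained by REINFORCE with a
    moving-average baseline against the validation loss of a value-weighted
    double-head 1D-CNN predictor. Includes sliding-window preprocessing,
    a synthetic HAR-like signal generator with seeded label corruption,
    and the corrupted-sample-discovery (CSD) and remove-high/low-value-sample
    (RHLVS) evaluation curves with their reference classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
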