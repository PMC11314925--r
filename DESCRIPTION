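Package: sonoforce
Title: Force Prediction from Distributed M-Mode Muscle Ultrasound
Version: 0.1.0
Authors@R:
    person("sonoforce", "developers", email = "sonoforce@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for predicting ground reaction
    force from M-mode musculoskeletal ultrasound. Provides a synthetic
    speckle phantom of contracting thigh muscles, a frequency-sweep (FMCW)
    acquisition model that encodes tissue depth as beat frequency and
    recovers A-lines by FFT demodulation, windowed intensity-weighted
    mean-depth feature extraction with z-scoring and PCA truncation,
    closed-form ridge regression of force on image features, and a
    cross-validated six-model comparison protocol with held-out-trial
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
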