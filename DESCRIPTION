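Package: gaitablate
Title: Sensor Ablation Analysis for Wearable-Sensor Activity Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates multimodal treadmill gait sessions (surface EMG,
    accelerometers, force plates, belt speed), extracts windowed signal
    features, labels activities from smoothed speed with per-subject
    thresholds, compares principal-component subspaces across trials via
    folded component angles, classifies standing/walking/running/sprinting
    with a Gaussian-kernel support vector machine under leave-one-trial-out
    cross-validation, and quantifies sensor-subset ablation with Cohen's d
    effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
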