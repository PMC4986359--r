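Package: myodecode
Title: Myoelectric Motion Decoding with Muscle Synergies and Extreme
    Learning Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A simulation and analysis pipeline for real-time myoelectric
    intent decoding from multi-channel surface electromyography (EMG).
    Provides a synthetic EMG session generator with planted muscle-synergy
    structure, envelope preprocessing (rectification and low-pass
    filtering), sliding-window time-domain features (mean absolute value
    and uncentered variance), muscle-synergy extraction by non-negative
    matrix factorization with automatic synergy-count selection,
    a from-scratch extreme learning machine classifier with closed-form
    ridge training and cross-validated hidden-layer sizing, a simulated
    online testing phase driving a minimum-jerk virtual arm, and the
    standard offline and online decoder performance metrics (accuracy,
    motion selection and completion times, learning trend, trial-to-trial
    variability).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
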