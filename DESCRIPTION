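Package: vigicouple
Title: Cortico-Autonomic Coupling and Fluctuation Analysis at the
    Wake-Sleep Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the coupling between cortical arousal
    (1-Hz EEG-vigilance stage series) and autonomic signals (heart rate,
    skin conductance level) during extended resting-state recordings.
    Implements lagged cross-correlation coupling metrics (maximal
    coefficient and delay), a tent-kernel fluctuation-period estimator
    with amplitude-thresholded cycle detection, auditory oddball
    event-related potential (N1/P2) averaging and peak extraction, the
    associated correlation and two-group statistics (Welch and pooled t,
    Cohen's d, chi-square, Mann-Whitney), and a synthetic generator of
    coupled vigilance/heart-rate/skin-conductance recordings with known
    ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
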