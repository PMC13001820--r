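Package: reachsacc
Title: Microsaccade Modulation During Goal-Directed Reaching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for joint eye-hand analyses of
    microsaccadic modulation during goal-directed reaching. Provides a
    synthetic-data generator for four-condition delayed-response trials
    (cue monitoring, cursor tracking, visible and invisible reaches) with
    ground-truth microsaccades and minimum-jerk kinematics; zero-phase
    Butterworth preprocessing and 500-to-1000 Hz upsampling; velocity-based
    microsaccade detection with elliptic median-SD thresholds; kinematic
    hand-movement segmentation with percent-of-peak criteria; rule-based
    trial exclusion; state-based and causal-kernel microsaccade-rate
    estimation over named analysis zones; and repeated-measures ANOVA,
    post hoc and paired-t reporting on zone summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
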