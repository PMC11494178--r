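Package: clickbci
Title: Offline Toolkit for Click-Based Electrocorticographic Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating a click-based brain-computer
    interface from multichannel electrocorticographic (ECoG) recordings:
    calibration-normalized high-gamma (110-170 Hz) spectral features on a
    100 ms cadence, shift-only time-warp realignment of training trials,
    rest/grasp labeling with contiguous balanced cross-validation folds, a
    many-to-one LSTM fully-connected classifier written in base R, a
    voting-window click detector with a refractory lock-out, a switch-scanning
    speller simulator with a pluggable autocomplete engine, event-based
    performance metrics (sensitivity, true/false positive frequencies, click
    latencies, spelling rates) with BCa bootstrap confidence intervals and
    rank-sum comparisons, and integrated-gradients channel saliency. A
    seeded synthetic ECoG generator emulates the statistical structure the
    pipeline assumes so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
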