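Package: saveseq
Title: Simulation and Analysis of Neural Progress Coding in Sequential
    Save-Spend Choice Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how single neurons track progress through
    self-determined economic choice sequences. Provides a generator for
    synthetic saving-task experiments (behavior, reaction times, and
    Poisson spike trains under ground-truth tuning models), subjective-value
    computations for geometric reward accumulation, fixed-window and
    sliding-window spike-count regression with bootstrap run-length
    calibration, paired tuning-model contests, population adaptation
    analyses of length-normalized progress coding, and pseudo-population
    decoding of sequence progress with nearest-neighbor and linear
    max-margin classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    generics,
    ggplot2,
    e1071,
    jsonlite,
    readr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
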