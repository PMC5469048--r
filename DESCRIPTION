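Package: vmlearn
Title: Simulating and Contesting Visuomotor Learners of Zeroth, First and
    Second Order
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the order of complexity of visuomotor
    learning with a target-shooting task under random magnify-and-shift
    joystick-to-cursor mappings.  Implements three optimized adaptive
    learners (zeroth-order node perturbation, first-order least mean
    squares, second-order recursive least squares), subject-matched
    calibration of initial accuracy and response variability, Nelder-Mead
    hyperparameter optimization on simulated end-of-block error, a
    synthetic-subject cohort generator, and the brute-force Monte-Carlo
    contest statistics (early error over shots 3-7, empirical p-values,
    group and per-shot contests, variability-scaling robustness checks).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
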