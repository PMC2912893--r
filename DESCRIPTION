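Package: qpcreff
Title: Amplification-Efficiency Estimation and Efficiency Clustering for
    Low-Density qPCR Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-primer amplification efficiency from serial-dilution
    CT tables by log2-dilution regression, attaches transformed confidence
    intervals to each efficiency estimate, purges unreliable primers (missing
    values, insignificant slopes, transformed-CI-length outliers by the 1.5xIQR
    rule), clusters the surviving primers into a small number of efficiency
    groups with a grouped-slope model selected by nested F-tests, and produces
    efficiency-adjusted CT values, relative-expression ratios and adjusted
    fold-change dispersion profiles for comparing correction schemes. Includes
    a synthetic serial-dilution generator with known ground truth and a
    command-line entry point for the full workflow.
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
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
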