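Package: tfpulse
Title: Transcription-Factor Activity Inference from Two-Color Microarray Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for time-resolved transcription-factor
    (TF) activity analysis of two-color microarray experiments. Covers
    preprocessing of two-channel intensity tables (dye-swap aware log-ratio
    computation and per-array LOWESS normalization), per-time-point
    differential-expression calling with a fold-change and t-test gate,
    network-constrained TF activity inference under a log-linear Gaussian
    factor model fitted by mean-field variational Bayes, and a cross-condition
    comparison of inferred TF profiles by absolute Pearson correlation with a
    sentinel score for condition-specific responses. Includes a synthetic-data
    generator emulating a dye-swap time-course design so the whole pipeline is
    testable without external data.
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
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
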