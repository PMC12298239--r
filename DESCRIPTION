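Package: tremorband
Title: Band-Limited Spectral Analysis of Physiological Tremor Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for analysing lower-limb physiological tremor from
    single-axis accelerometer recordings. Estimates power spectral density by
    averaging Hann-windowed FFT periodograms over contiguous signal segments,
    computes band log-amplitude and mean-frequency (spectral centroid) tremor
    indices over configurable frequency bands, and provides the cohort
    statistical layer used in neuromuscular fatigue studies: two-within-factor
    repeated-measures ANOVA with partial eta squared, Tukey post hoc
    contrasts, and summary-statistic t-tests with Cohen's d. Includes a
    seeded synthetic tremor and cohort generator with exported ground truth
    so every stage is testable without raw recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    car,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
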