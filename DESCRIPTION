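Package: sedclust
Title: Diurnal Sedentary-Behavior Typologies from Minute-Epoch Accelerometer Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify typologies of diurnal sedentary-behavior
    patterns from minute-epoch accelerometer METs series: epoch intensity
    classification and non-wear detection, per-day wear validation, sedentary
    bout and break metrics by time of day, the diurnal variation-level
    statistic, two-step clustering (Ward agglomeration followed by
    deterministic k-means refinement), and cluster profiling via one-way
    ANOVA with Bonferroni post hoc tests and chi-square tests with adjusted
    standardized residuals. Includes a synthetic cohort generator with known
    cluster structure for end-to-end validation.
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
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
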