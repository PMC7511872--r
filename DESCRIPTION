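Package: circastress
Title: Circadian Heart Rate and Chronic Stress Modelling for Wearable Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying how chronic stress, gender and age modulate
    the circadian rhythm of heart rate measured by chest-worn wearables.
    Provides a synthetic cohort generator for minute-level heart-rate and
    accelerometer streams, accelerometer-based non-wear/malfunction
    detection, physiological artifact filtering and hourly aggregation, a
    four-harmonic (cosinor) linear mixed-effects model with AR(1) residual
    correlation fitted by maximum likelihood, likelihood-ratio model
    comparison, Table-1 style descriptive statistics, and an end-to-end
    reproducible pipeline with reporting plots.
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
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
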