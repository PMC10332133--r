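Package: pollenscale
Title: Pollen Deposition Grading Scales from Dose-Response Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds graded pollen-exposure warning scales from daily
    multi-station pollen deposition records and daily allergic-patient
    counts. Provides city-average series construction, trailing
    moving-average exposure windows, pollen-season detection by cumulative
    bounds, Spearman-based exposure-window selection, a shifted-logarithm
    dose-response fit with its first derivative, empirical deposition
    percentiles and patient-quantile threshold inversion, and a five-level
    grading scale with per-level patient-increment bands. A synthetic-data
    module emulates a multi-year, multi-station surveillance design so the
    whole pipeline is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests: jsonlite, knitr, rmarkdown, testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
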