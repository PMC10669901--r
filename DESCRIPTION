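Package: ibrtox
Title: Integrated Biomarker Response and Factorial ANOVA for
    Multi-Stressor Ecotoxicology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing oxidative-stress biomarker batteries from
    crossed multi-stressor exposure experiments. Implements the integrated
    biomarker response index (IBR/IBRv2: log-ratio transformation,
    standardization, deviation from a reference condition, and summation,
    with star-plot geometry), balanced three-way fixed-effects analysis of
    variance with Tukey HSD post hoc comparisons and compact letter
    displays, Levene's homogeneity test, Pearson correlation matrices, and
    principal component analysis of condition-level biomarker profiles. A
    seeded synthetic-data generator emulates a temperature-by-toxicant
    factorial design with multiplicative lognormal noise for calibration
    and power studies, and a pipeline orchestrator produces reproducible
    tabular and graphical outputs from a single configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
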