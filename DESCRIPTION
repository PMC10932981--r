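Package: dichoptics
Title: Binocular Gain-Control Modelling and Adaptive Psychophysics Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing binocular-vision psychophysics experiments
    built around a two-stage interocular contrast gain-control model.
    Provides transformed up-down staircase simulation, logistic psychometric
    function fitting with threshold and balance-point estimation, closed-form
    and simplex fitting of per-eye gains and interocular suppression weights
    from detection and dichoptic-masking thresholds, derived suppression
    strength and sensory eye-imbalance measures, synthetic simulated-observer
    cohorts for end-to-end validation, and the group-level statistical
    battery (Mann-Whitney, Spearman, Fisher r-to-z, two-way ANOVA with
    Bonferroni post hocs, and Wilcoxon-Mann-Whitney power).
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
    MASS,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
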