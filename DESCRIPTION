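Package: evresilience
Title: Extracellular-Vesicle Feature Profiling for Resilience Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of imaging-flow-cytometry extracellular-
    vesicle (EV) feature exports for discriminating high- from low-resilience
    individuals. Reduces per-event feature tables to a 1116-variable
    per-sample profile (feature x channel x size stratum x statistic),
    selects candidate variables with least-squared-deviation regression
    trees fitted against a continuous resilience score, compares groups
    with normality-routed parametric or exact non-parametric tests and
    Hedges' g effect sizes, and evaluates diagnostic accuracy with ROC
    curves, the Youden index and positive likelihood ratios. Includes a
    synthetic cohort generator that emulates the assumed data structure
    (per-event lognormal intensities with subject-level random effects,
    size-mixture areas, implantable group-by-timepoint effects, biomarker
    and nanoparticle-tracking panels) so the whole pipeline is testable
    without access to subject-level data.
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
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
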