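Package: lifescores
Title: Lifestyle and Malnutrition Risk Scores with Cohort Survival Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calculators for questionnaire-based lifestyle scores and
    laboratory-based malnutrition indices (CONUT, PNI, NRI) together with the
    Framingham 10-year coronary heart disease risk score, tercile
    stratification and cross-tabulation of scored cohorts, covariate-adjusted
    group comparisons and score correlations, Cox proportional-hazards
    mortality models with age-group effect modification, and paired
    longitudinal lipid-change analysis. Includes a seeded synthetic cohort
    generator emulating a large population-based adult cohort so that every
    analysis stage can be exercised and calibrated without access-restricted
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
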