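# lifescores

Lifestyle and malnutrition risk scores with cohort survival analysis.

`lifescores` implements the statistical machinery of a population-based
cohort analysis linking a questionnaire-derived **Lifestyle Score (LS)** to
malnutrition screening indices, cardiovascular risk and all-cause mortality.
It is aimed at epidemiologists and biostatisticians who want the complete
pipeline — score calculators, tercile stratification, adjusted group
comparisons, Cox survival models with age-group effect modification, and
paired longitudinal change analysis — as tested, composable R functions.
Because the motivating cohort data are access-restricted, the package ships
a seeded synthetic cohort generator that emulates the published marginal
structure, so every stage can be exercised, calibrated and validated by
simulation.

## The scores

* **Lifestyle Score (LS)** = diet + physical activity + smoking + alcohol
  sub-scores (lower = healthier; range 3–66 under the default schema).
  Fixed terciles: LS ≤ 21 (T1, healthiest), 22–32 (T2), > 32 (T3). Alcohol
  intake above 10 g/day (women) or 20 g/day (men) receives the less
  favourable points.
* **CONUT** (Controlling Nutritional Status) = banded points for serum
  albumin (g/L), total cholesterol (mmol/L) and lymphocyte count (10⁹/L);
  integer range 0–12, grouped 0 / 1–2 / ≥ 3 into low / moderate / high
  malnutrition risk.
* **PNI** (Prognostic Nutritional Index) = 10 × albumin (g/dL) +
  0.005 × lymphocytes (per mm³); lower = higher risk; bands
  > 56.35 / 53.25–56.35 / < 53.25.
* **NRI** (Nutritional Risk Index) = 1.489 × albumin (g/L) +
  41.7 × weight / ideal weight, with the sex-specific **Lorenz** ideal
  weight; bands > 122.8 / 115.2–122.8 / < 115.2.
* **Framingham 10-year CHD risk** from the categorical (point-sheet) model:
  age, sex, total- or LDL-cholesterol band, HDL, blood-pressure category,
  diabetes, smoking; categories < 5 / 5–10 / 10–20 / > 20 %.

The survival stage fits Cox proportional-hazards models (Efron ties;
tercile factors coded against the unfavourable reference), checks
proportionality via Schoenfeld residuals, and tests effect modification of
the standardized score LS_z by age group (< 60 / 60–69 / ≥ 70) with a 2-df
likelihood-ratio test plus per-stratum hazard ratios.

## Worked example

```r
library(lifescores)

cohort <- generate_cohort(sim_config(n = 2000, seed = 42))
scored <- score_cohort(cohort)

dplyr::count(scored, ls_tercile)
#>   ls_tercile     n
#> 1 T1           641
#> 2 T2           754
#> 3 T3           605

fit <- cox_fit(scored, c("conut", "age", "sex", "bmi"))
tidy(fit)
#>   term        beta     se    hr conf_low conf_high  p_value
#> 1 conut   -0.274   0.140  0.760    0.578      1.00 5.01e- 2
#> 2 age      0.112   0.0120 1.12     1.09       1.15 5.76e-21
#> 3 sexmale  0.568   0.214  1.76     1.16       2.68 7.91e- 3
#> 4 bmi      0.00323 0.0220 1.00     0.961      1.05 8.83e- 1
```

The default generator carries *no* true CONUT–mortality effect, so the
CONUT hazard ratio hovers around 1 while the built-in age (HR 1.12/year)
and male-sex (HR 1.76 here, truth 1.6) effects are recovered; `glance(fit)`
reports 92 events among 2000 participants and a global Schoenfeld p of
0.59 (no proportionality violation). Cross-tabulation and the longitudinal
stage chain the same way:

```r
xt <- cross_tabulate(scored, "ls_tercile", "conut_group")
chi_square_independence(xt)
#>   statistic    df p_value
#> 1      2.41     4   0.661

paired_difference_summary(scored) |>
  dplyr::filter(variable == "triglycerides")
#>   group   n mean_base mean_follow mean_diff sd_diff_approx  p_value
#> 1    T1 279      1.29        1.74    -0.452           1.66 1.4e-08
#> 2    T2 304      1.42        1.95    -0.528           1.69 5.8e-15
#> 3    T3 265      1.60        2.33    -0.731           2.46 6.7e-14
```

Negative mean differences (baseline − follow-up) show the simulated
triglyceride rise, largest in the least healthy tercile, each highly
significant by the paired Wilcoxon signed-rank test. A one-command
replication of the full analysis (scoring, descriptives, correlations, Cox
fits, age-interaction, longitudinal report, CSV bundle + manifest) is
`run_pipeline(pipeline_config(out_dir = "out"))`.

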