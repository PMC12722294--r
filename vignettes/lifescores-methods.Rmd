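---
title: "Methods: scores, synthetic cohort and survival analysis in lifescores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scores, synthetic cohort and survival analysis in lifescores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifescores)
```

# Overview

`lifescores` packages the statistical pipeline of a cohort analysis that
relates a questionnaire-based Lifestyle Score (LS) to malnutrition
screening indices (CONUT, PNI, NRI), Framingham 10-year coronary risk and
all-cause mortality. This vignette is the package's own account of the
methods: the score definitions and their unit contracts, the synthetic
cohort generator and what it does and does not emulate, the survival and
longitudinal models, and the numerical and design choices made where the
published description left the design open.

# Score engine

## Lifestyle Score

The LS is the plain sum of four questionnaire sub-scores (diet, physical
activity, smoking, alcohol), each in points with *lower = healthier*. The
item-level scoring of the questionnaires is not part of this package: the
sub-scores are pipeline inputs, and any record missing one of them is
excluded from LS analyses (complete-case, mirrored by `NA` propagation in
`lifestyle_score()`). Fixed terciles are LS ≤ 21 / 22–32 / > 32; the
boundary convention is "closed below" (a score of exactly 21 is T1). The
alcohol sub-score penalizes intake above 10 g/day for women and 20 g/day
for men (`alcohol_subscore_band()`); intake exactly at the threshold is not
penalized, since only *exceeding* intake counts as higher consumption.

The sub-score schema that the simulator uses as its default was chosen so
the LS spans 3–66: diet 1–20, physical activity 1–16, smoking 0–15
(0 = non-smoker), alcohol 1–15 points. The published account keeps the
exact point assignments in supplementary material; because no analysis in
this package depends on the internal composition — only on the sum and its
terciles — any schema with the right range and population moments is
adequate for validation, and ours is deliberately simple.

## CONUT, PNI, NRI

CONUT sums three banded labs. The published table prints the band edges but
not every point weight, so the canonical scheme is shipped as editable
configuration (`conut_bands()`): albumin ≥ 35 g/L → 0, 30–34.9 → 2,
25–29.9 → 4, < 25 → 6; cholesterol ≥ 4.65 mmol/L → 0, 3.62–4.64 → 1,
2.59–3.61 → 2, < 2.59 → 3; lymphocytes ≥ 1.6·10⁹/L → 0, 1.2–1.59 → 1,
0.8–1.19 → 2, < 0.8 → 3. Band edges are closed on the healthy side. Risk
groups are 0 / 1–2 / **≥ 3** (the "≥ 3 = high" reading was adopted where
the printed table's "> 3" conflicts with the text).

PNI is stated with albumin in g/L in one place and g/dL in another; only
g/dL is consistent with the published cohort mean (PNI ≈ 55.2 at albumin
45.8 g/L and lymphocytes 1.88·10⁹/L), so `pni_score()` converts the g/L
storage unit internally: PNI = albumin[g/L] + 5 × lymphocytes[10⁹/L].

NRI replaces the classic "usual weight" denominator by the Lorenz ideal
weight from height and sex. The classic NRI caps the weight ratio at 1;
here it is deliberately *uncapped*, because the published cohort mean
(≈ 119.9) is only reachable with ratios above 1. The Lorenz formula is
undefined in spirit below 150 cm; such heights are still computed but
flagged with a warning.

A plausibility gate guards the albumin unit contract: a cohort whose
median albumin falls outside roughly 20–60 g/L triggers a g/dL-suspicion
warning rather than silently producing garbage scores.

## Framingham risk

The published analysis used an unnamed online calculator; this package
implements the categorical point-sheet model (Wilson 1998) with both the
total-cholesterol and LDL variants, defaulting to total cholesterol. The
full point tables — age bands, lipid bands in mg/dL (inputs in mmol/L are
converted with the factor 38.67), HDL bands, the blood-pressure category
taken as the *higher* of the systolic and diastolic categories, diabetes
and smoking points, and the point-total → percent-risk lookups — ship as
inspectable data in `framingham_points()`. Ages outside the tabulated
30–74 range are clamped to the nearest band (the cohort spans 18–80), and
point totals beyond the printed sheet are clamped to its ends. Risk
categories use < 5 / [5, 10) / [10, 20] / > 20 percent. On the default
synthetic cohort the mean risk comes out near 8 %, consistent with the low
to moderate published cohort average (~7.4 %) — a soft calibration check,
not a fitted quantity.

# Synthetic cohort generator

The real cohort is access-restricted, so `generate_cohort()` draws a
synthetic stand-in whose *analysis-relevant* structure matches the
published marginals:

* n = 6073, 51.8 % women; age truncated-normal 55.5 ± 12.3 on [18, 80];
* sex-specific height and BMI normals (weight derived), labs at the
  published means/SDs — albumin 45.8 ± 2.45 g/L, total cholesterol
  5.58 ± 1.07 mmol/L, LDL 3.51 ± 0.96; lymphocytes and triglycerides
  lognormal (right-skewed, as in real laboratory data);
* HDL decreasing (1.72 / 1.61 / 1.52 mmol/L) and triglycerides increasing
  (1.24 / 1.37 / 1.56 mmol/L) across LS terciles, imposed directly as
  per-tercile distributions;
* lifestyle sub-scores drawn around sex- and age-shifted means with a
  shared latent "lifestyle propensity" factor, which induces the positive
  sub-score correlations needed to reach the published LS dispersion
  (mean ≈ 27.6, SD ≈ 10.8 against the published 27.6 ± 11.2) rather than
  modelling a full covariance matrix. Structural regressions of this kind
  were preferred over a copula because only the analysis-relevant
  gradients have to hold.

Mortality follows a proportional-hazards process: the cumulative hazard is
`rate · t^shape · exp(η)` (shape 1, i.e. exponential, by default, so
closed-form checks are available), with η a sum of *centred* covariate
effects — age (default HR 1.09/year, a realistic adult all-cause slope),
male sex (HR 1.6), and optional score effects (per CONUT point, per LS SD,
or per LS tercile within age group). Death times come from the inverse
cumulative-hazard transform; administrative censoring truncates follow-up
at 110 months (the registry-query design), and 2 % of participants are
censored early at a uniform time ("withdrawn"). The default baseline rate
2.5·10⁻⁴/month was chosen once so that roughly 4 % of the cohort dies
inside the window, the healthy-cohort regime the analysis assumes; the
realized fraction with the default effects is ≈ 4.0 %.

The paired follow-up lipids are generated for a random 2530/6073
subsample as baseline − (per-tercile shift) + noise, with the shifts and
noise SDs set to the published per-tercile mean differences and
SD-of-difference values, so the longitudinal stage sees the right sign
pattern (cholesterol and HDL decline, triglycerides rise, most strongly in
T3).

**What the generator does not emulate:** recruitment stratification and
non-response, medication effects on labs, measurement error and attrition
structure between waves, the J-shaped alcohol–risk relationship, any
correlation between labs and lifestyle beyond the configured HDL/TG
gradients, and cause-specific mortality. Passing simulation-based tests
therefore demonstrates that the *machinery* recovers known truth under the
assumed data-generating process — not that the published real-data
estimates are correct.

# Descriptive and comparative statistics

Cross-tabulations report counts and row percentages on the non-missing
pairs, with incomplete pairs dropped and counted; row percentages are kept
at full precision internally and rounded to one decimal only for display.
Independence is tested with the Pearson chi-square without continuity
correction (expected counts below 5 trigger a warning). Adjusted group
comparisons follow the published procedure: OLS ANCOVA with the group as a
factor plus covariates (age and sex; lipids additionally BMI), a type-II F
test for the group effect, and Tukey-adjusted pairwise contrasts of the
estimated marginal means. Skewed outcomes use Kruskal–Wallis (≥ 3 groups)
or the Wilcoxon rank-sum test. Correlations use Spearman/Pearson for the
LS–Framingham surface (including the smoking-excluded LS variant, which
isolates the shared smoking component) and Kendall's τ for the heavily
tied discrete sub-scores against the malnutrition indices. Following the
published analysis policy, all tests are two-sided at α = 0.05 with **no**
multiplicity correction; raw p-values are reported.

Empirical terciles use type-1 (inverse-ECDF) quantiles with boundaries
assigned to the lower group, matching the "≤ 21" convention of the fixed
scheme; constant input yields a flagged degenerate scheme rather than an
error.

# Survival analysis

Kaplan–Meier curves are product-limit estimates with a log-rank test
across groups (undefined, with a warning, when there are no events). Cox
models use the Efron approximation for ties — event times on a monthly
grid are heavily tied, so Breslow would be noticeably biased — and report
hazard ratios with Wald 95 % CIs. Tercile-coded scores are releveled so
the unfavourable (3rd/high) group is the reference, matching the
published table layout; reversing the reference simply inverts the HRs.
The default adjustment set is {age, sex, BMI}; the published text
mentions MACE in one place, so covariate sets are an argument, not a
constant. Proportionality is checked with scaled Schoenfeld residual
tests per covariate and globally.

The age-interaction procedure standardizes the LS to z-scores over the
analysis sample (`standardize_ls()`), forms age groups < 60 / 60–69 / ≥ 70
(left-closed: 60 belongs to 60–69, 70 to ≥ 70), and compares nested Cox
models with and without the two `LS_z × age group` interaction terms by a
likelihood-ratio test (statistic = 2·Δ partial log-likelihood, df = 2).
Stratum-specific models (adjusted for sex and BMI, as in the published
figure) report the HR per 1-SD worse lifestyle per age group, and within
the oldest stratum the tercile HRs against T1. Continuous-score and
tercile-coded models are fitted separately throughout (the published
report is ambiguous; separate fits are the conventional reading).

The Cox solver itself is delegated to the `survival` package — the
standard, heavily validated implementation — while the reference coding,
standardization, stratification, LRT and the simulation-recovery harness
are implemented here; a brute-force one-dimensional partial-likelihood
maximizer serves as an independent oracle in the test suite (agreement to
1e-6 on small no-tie data).

# Longitudinal change

The paired analysis restricts to participants with both waves. The
difference is `baseline − follow-up` (positive = decline over time). Two
dispersion summaries are reported: the exact SD of the per-person
differences, and the independence approximation
`sqrt(SD_base² + SD_follow²)` (`sd_of_difference()`) that the published
table footnote uses — the latter is what reproduces the printed cells from
printed per-wave SDs. Within-group change is tested with the paired
Wilcoxon signed-rank test using **Pratt's** treatment of zero differences
(zeros are ranked, then removed from the null mean/variance), which is
robust for granular laboratory values; small samples without zeros or ties
use the exact distribution, larger ones the tie-corrected normal
approximation. Between-tercile comparisons of the per-person changes use
rank-sum tests for the three pairings.

# Numerical choices and degenerate inputs

* Boundary membership: LS cuts closed below (21 → T1); PNI/NRI boundary
  values belong to the moderate band; Framingham categories
  [5, 10) / [10, 20] / > 20; CONUT band edges closed on the healthy side.
* All randomness flows from a single integer seed
  (`withr::with_seed`), making cohorts byte-identical under a fixed
  config + seed; pipeline reruns produce identical numeric CSVs.
* Degenerate inputs return flagged results rather than crashing where a
  downstream consumer can proceed (empty tercile → `n = 0`/`NA` rows;
  constant outcome → p = 1 with warning; no events → flat KM curves with
  `NA` log-rank), and error informatively where it cannot (singular ANCOVA
  design names the aliased term; zero SD in standardization; zero
  marginals in the chi-square).

# Problem sizes used in validation

The test suite exercises the recovery properties at sizes chosen to give
sharp checks at interactive runtimes: 50 replicates of n = 6073 for the
continuous-CONUT and oldest-stratum tercile HR recoveries (median estimate
within 5 % and 10 % of truth respectively, CI coverage ≥ 90 %); 400
replicates at n = 1500 with the baseline hazard scaled to ≈ 120 events per
replicate for the type-I calibration of the interaction LRT (rejection
rate ≈ 5 %); 1000-record random panels for the score-oracle equivalences;
and 5–6-person toy datasets for the hand-checked Kaplan–Meier and
brute-force Cox comparisons.

# Known limitations

* The Framingham point tables are a reconstruction of the published
  categorical sheets; other calculators (including whichever online tool
  the original analysis used) differ by a few points in edge cells.
* The LS sub-score schema is a stand-in with the right range and moments,
  not the questionnaire's actual item scoring.
* The generator's lab–lifestyle dependence is limited to the configured
  HDL/TG gradients; correlation-based results on synthetic data should be
  read as machinery checks only.
* Cause-specific and competing-risk mortality are out of scope, as in the
  motivating analysis.
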