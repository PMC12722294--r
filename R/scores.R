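#' Lifestyle score: sum of the four lifestyle sub-scores
#'
#' The lifestyle score (LS) is the arithmetic sum of the diet, physical
#' activity, smoking and alcohol sub-scores, each derived from self-report
#' questionnaires. Lower values correspond to a healthier lifestyle; with the
#' default sub-score schema the score spans 3 to 66. Sub-scores are pipeline
#' inputs here - the questionnaire item scoring itself is out of scope.
#'
#' @param diet,pa,smoking,alcohol numeric sub-scores (points, >= 0).
#' @return Numeric LS values; `NA` where any sub-score is missing
#'   (complete-case convention).
#' @examples
#' lifestyle_score(5, 6, 4, 6) # 21, the upper edge of the healthiest tercile
#' @export
lifestyle_score <- function(diet, pa, smoking, alcohol) {
  for (v in list(diet, pa, smoking, alcohol)) {
    if (any(v < 0, na.rm = TRUE)) abort("sub-scores must be >= 0")
  }
  diet + pa + smoking + alcohol
}

#' Lifestyle score without the smoking component
#'
#' Used to check whether the LS-Framingham association is driven by smoking,
#' which both scores share.
#'
#' @inheritParams lifestyle_score
#' @return Numeric diet + physical activity + alcohol sum.
#' @export
ls_excluding_smoking <- function(diet, pa, alcohol) {
  for (v in list(diet, pa, alcohol)) {
    if (any(v < 0, na.rm = TRUE)) abort("sub-scores must be >= 0")
  }
  diet + pa + alcohol
}

#' @rdname ls_scheme
#' @param ls numeric lifestyle-score values.
#' @param scheme tercile scheme; defaults to the fixed published cut-offs.
#' @export
ls_category <- function(ls, scheme = ls_scheme()) {
  cut_terciles(ls, scheme)
}

#' Sex-specific alcohol intake band
#'
#' Daily alcohol intake above 10 g/day for women or 20 g/day for men is
#' classified as higher consumption and receives the less favourable
#' alcohol points; intake at or below the threshold is not penalized.
#'
#' @param intake alcohol intake in g/day (>= 0).
#' @param sex `"male"` or `"female"` (recycled as needed).
#' @param thresholds named vector of g/day cut-offs.
#' @return Factor `"not_penalized"` / `"penalized"`.
#' @export
alcohol_subscore_band <- function(intake, sex,
                                  thresholds = c(female = 10, male = 20)) {
  if (any(intake < 0, na.rm = TRUE)) abort("alcohol intake must be >= 0")
  sex <- as.character(sex)
  if (!all(sex %in% c(names(thresholds), NA))) {
    abort("`sex` must be one of: ", paste(names(thresholds), collapse = ", "))
  }
  penalized <- intake > unname(thresholds[sex])
  factor(ifelse(penalized, "penalized", "not_penalized"),
    levels = c("not_penalized", "penalized")
  )
}

#' CONUT band tables
#'
#' Point weights per laboratory band for the Controlling Nutritional Status
#' score, stored as editable configuration. Bands are half-open on the
#' healthy side (`[lower, upper)` walking down from the healthiest band), so
#' e.g. albumin exactly 35 g/L scores 0 and cholesterol exactly 4.65 mmol/L
#' scores 0.
#'
#' @return Named list with one tibble per analyte (`breaks` are the lower
#'   edges of the bands above the worst one; `points` run worst to best).
#' @export
conut_bands <- function() {
  list(
    albumin = tibble(breaks = list(c(25, 30, 35)), points = list(c(6, 4, 2, 0)),
                     unit = "g/L"),
    cholesterol = tibble(breaks = list(c(2.59, 3.62, 4.65)),
                         points = list(c(3, 2, 1, 0)), unit = "mmol/L"),
    lymphocytes = tibble(breaks = list(c(0.8, 1.2, 1.6)),
                         points = list(c(3, 2, 1, 0)), unit = "10^9/L")
  )
}

band_points <- function(x, band) {
  idx <- findInterval(x, band$breaks[[1]])
  band$points[[1]][idx + 1L]
}

#' CONUT score (Controlling Nutritional Status)
#'
#' Sum of three banded laboratory components - serum albumin (g/L), total
#' cholesterol (mmol/L) and lymphocyte count (10^9/L) - giving an integer
#' score from 0 (normal) to 12 (severe malnutrition risk).
#'
#' @param albumin serum albumin in g/L.
#' @param cholesterol total cholesterol in mmol/L.
#' @param lymphocytes lymphocyte count in 10^9 cells/L.
#' @param bands band configuration, see [conut_bands()].
#' @return Integer CONUT points in `[0, 12]`; `NA` where any lab is missing.
#' @examples
#' conut_score(45, 5.0, 1.8) # all labs in the healthiest band -> 0
#' conut_score(24, 2.0, 0.5) # all labs in the worst band -> 12
#' @export
conut_score <- function(albumin, cholesterol, lymphocytes,
                        bands = conut_bands()) {
  for (v in list(albumin, cholesterol, lymphocytes)) {
    if (any(v < 0, na.rm = TRUE)) abort("laboratory values must be >= 0")
  }
  check_albumin_units(albumin)
  as.integer(
    band_points(albumin, bands$albumin) +
      band_points(cholesterol, bands$cholesterol) +
      band_points(lymphocytes, bands$lymphocytes)
  )
}

#' CONUT risk group
#'
#' 0 points = low, 1-2 = moderate, >= 3 = high malnutrition risk. The cohort
#' is too healthy for empirical CONUT terciles, hence these fixed categories.
#'
#' @param conut integer CONUT points in `[0, 12]`.
#' @return Factor `low` / `moderate` / `high`.
#' @export
conut_group <- function(conut) {
  if (any(conut < 0 | conut > 12, na.rm = TRUE)) {
    abort("CONUT points must lie in [0, 12]")
  }
  idx <- 1L + (conut >= 1) + (conut >= 3)
  factor(c("low", "moderate", "high")[idx],
    levels = c("low", "moderate", "high")
  )
}

#' Prognostic nutritional index (PNI)
#'
#' PNI = 10 x albumin (g/dL) + 0.005 x lymphocyte count (per mm^3). Inputs
#' are taken in the cohort storage units (albumin g/L, lymphocytes 10^9/L)
#' and converted internally (g/L / 10; 10^9/L x 1000). Lower PNI indicates a
#' higher malnutrition risk.
#'
#' @inheritParams conut_score
#' @return Numeric PNI points.
#' @examples
#' pni_score(45.8, 1.88) # 55.2
#' @export
pni_score <- function(albumin, lymphocytes) {
  if (any(albumin < 0, na.rm = TRUE) || any(lymphocytes < 0, na.rm = TRUE)) {
    abort("laboratory values must be >= 0")
  }
  check_albumin_units(albumin)
  10 * (albumin / 10) + 0.005 * (lymphocytes * 1000)
}

#' @rdname ls_scheme
#' @param pni numeric PNI values.
#' @export
pni_group <- function(pni, scheme = pni_scheme()) {
  cut_terciles(pni, scheme)
}

#' Lorenz ideal body weight
#'
#' Sex-specific ideal weight from height: men
#' `(height - 100) - (height - 150)/4`, women
#' `(height - 100) - (height - 150)/2.5`. The formula is intended for heights
#' above 150 cm; shorter heights are still computed arithmetically but
#' flagged with a warning.
#'
#' @param height height in cm (> 0).
#' @param sex `"male"` or `"female"`.
#' @return Ideal body weight in kg.
#' @examples
#' lorenz_ideal_weight(170, "male") # 65
#' lorenz_ideal_weight(170, "female") # 62
#' @export
lorenz_ideal_weight <- function(height, sex) {
  if (any(height <= 0, na.rm = TRUE)) abort("height must be > 0")
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female", NA))) {
    abort("`sex` must be 'male' or 'female'")
  }
  if (any(height <= 150, na.rm = TRUE)) {
    warn("heights <= 150 cm are outside the regime the Lorenz formula targets")
  }
  divisor <- ifelse(sex == "male", 4, 2.5)
  (height - 100) - (height - 150) / divisor
}

#' Nutritional risk index (NRI)
#'
#' NRI = 1.489 x albumin (g/L) + 41.7 x (current weight / ideal weight),
#' with the Lorenz ideal weight in the denominator. The weight ratio is not
#' capped at 1, so well-nourished participants above their ideal weight can
#' exceed the classic 100-point ceiling. Lower NRI indicates a higher
#' malnutrition risk.
#'
#' @param albumin serum albumin in g/L.
#' @param weight current body weight in kg.
#' @param ideal_weight ideal body weight in kg (> 0), see
#'   [lorenz_ideal_weight()].
#' @return Numeric NRI points.
#' @export
nri_score <- function(albumin, weight, ideal_weight) {
  if (any(albumin < 0, na.rm = TRUE) || any(weight < 0, na.rm = TRUE)) {
    abort("albumin and weight must be >= 0")
  }
  if (any(ideal_weight <= 0, na.rm = TRUE)) abort("ideal weight must be > 0")
  1.489 * albumin + 41.7 * (weight / ideal_weight)
}

#' @rdname ls_scheme
#' @param nri numeric NRI values.
#' @export
nri_group <- function(nri, scheme = nri_scheme()) {
  cut_terciles(nri, scheme)
}

#' Framingham 10-year CHD risk category
#'
#' Four-way banding of the percent risk: `< 5` low, `[5, 10)` low-moderate,
#' `[10, 20]` moderate-high, `> 20` high.
#'
#' @param risk 10-year CHD risk in percent (`[0, 100]`).
#' @return Factor `low` / `low_moderate` / `moderate_high` / `high`.
#' @export
framingham_category <- function(risk) {
  if (any(risk < 0 | risk > 100, na.rm = TRUE)) {
    abort("risk must be a percentage in [0, 100]")
  }
  idx <- 1L + (risk >= 5) + (risk >= 10) + (risk > 20)
  factor(c("low", "low_moderate", "moderate_high", "high")[idx],
    levels = c("low", "low_moderate", "moderate_high", "high")
  )
}

#' Score a cohort: compute every score panel column
#'
#' Data-frame-first entry point of the score engine: takes a cohort table
#' (one row per participant, columns in the storage units documented in
#' [cohort_columns()]) and appends the full score panel - LS and its tercile,
#' CONUT and its risk group, PNI, NRI and their terciles, ideal weight, BMI,
#' and the Framingham 10-year CHD risk with its category. Each score is
#' computed on its own complete-case subset: rows missing an input of one
#' score get `NA` for that score only.
#'
#' @param data cohort tibble/data frame.
#' @param schemes named list of tercile schemes for `ls`, `pni`, `nri`.
#' @param framingham_mode `"tc"` (total cholesterol, default) or `"ldl"`.
#' @return The input with panel columns `ls`, `ls_no_smoking`, `ls_tercile`,
#'   `conut`, `conut_group`, `pni`, `pni_group`, `ideal_weight`, `nri`,
#'   `nri_group`, `bmi`, `framingham_risk`, `framingham_category` appended.
#' @examples
#' cohort <- generate_cohort(sim_config(n = 50, seed = 1))
#' scored <- score_cohort(cohort)
#' dplyr::count(scored, ls_tercile)
#' @export
score_cohort <- function(data,
                         schemes = list(ls = ls_scheme(), pni = pni_scheme(),
                                        nri = nri_scheme()),
                         framingham_mode = c("tc", "ldl")) {
  framingham_mode <- match.arg(framingham_mode)
  required <- c(
    "sex", "age", "height", "weight", "albumin", "total_cholesterol",
    "hdl", "triglycerides", "lymphocytes", "systolic_bp", "diastolic_bp",
    "diabetes", "smoker", "diet_subscore", "pa_subscore", "smoking_subscore",
    "alcohol_subscore"
  )
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    abort(paste("missing required columns:", paste(missing_cols, collapse = ", ")))
  }
  check_albumin_units(data$albumin)
  data |>
    mutate(
      ls = lifestyle_score(.data$diet_subscore, .data$pa_subscore,
                           .data$smoking_subscore, .data$alcohol_subscore),
      ls_no_smoking = ls_excluding_smoking(.data$diet_subscore,
                                           .data$pa_subscore,
                                           .data$alcohol_subscore),
      ls_tercile = ls_category(.data$ls, schemes$ls),
      conut = conut_score(.data$albumin, .data$total_cholesterol,
                          .data$lymphocytes),
      conut_group = conut_group(.data$conut),
      pni = pni_score(.data$albumin, .data$lymphocytes),
      pni_group = pni_group(.data$pni, schemes$pni),
      ideal_weight = lorenz_ideal_weight(.data$height, .data$sex),
      nri = nri_score(.data$albumin, .data$weight, .data$ideal_weight),
      nri_group = nri_group(.data$nri, schemes$nri),
      bmi = .data$weight / (.data$height / 100)^2,
      framingham_risk = framingham_risk(
        age = .data$age, sex = .data$sex,
        total_cholesterol = .data$total_cholesterol, hdl = .data$hdl,
        ldl = if ("ldl" %in% names(data)) .data$ldl else NA_real_,
        systolic_bp = .data$systolic_bp, diastolic_bp = .data$diastolic_bp,
        diabetes = .data$diabetes, smoker = .data$smoker,
        mode = framingham_mode
      ),
      framingham_category = framingham_category(.data$framingham_risk)
    )
}

#' Cohort data dictionary
#'
#' Names, units and roles of the columns the scoring and analysis functions
#' expect in a cohort table.
#'
#' @return A tibble with `column`, `unit`, `description`.
#' @export
cohort_columns <- function() {
  tribble(
    ~column, ~unit, ~description,
    "id", "", "participant identifier",
    "sex", "", "'male' or 'female'",
    "age", "years", "age at baseline",
    "height", "cm", "body height",
    "weight", "kg", "body weight",
    "albumin", "g/L", "serum albumin",
    "total_cholesterol", "mmol/L", "total cholesterol",
    "hdl", "mmol/L", "HDL cholesterol",
    "ldl", "mmol/L", "LDL cholesterol",
    "triglycerides", "mmol/L", "triglycerides",
    "lymphocytes", "10^9/L", "lymphocyte count",
    "systolic_bp", "mmHg", "systolic blood pressure",
    "diastolic_bp", "mmHg", "diastolic blood pressure",
    "diabetes", "", "diabetes status (logical)",
    "smoker", "", "current smoker (logical)",
    "diet_subscore", "points", "diet sub-score (lower = healthier)",
    "pa_subscore", "points", "physical-activity sub-score",
    "smoking_subscore", "points", "smoking sub-score",
    "alcohol_g_per_day", "g/day", "self-reported alcohol intake",
    "alcohol_subscore", "points", "alcohol sub-score",
    "mace", "", "history of cardiovascular events (logical)",
    "survival_months", "months", "follow-up time to death or censoring",
    "event", "", "death indicator (logical)",
    "censor_reason", "", "'admin', 'withdrawn' or NA for deaths"
  )
}
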