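test_that("lifestyle score is the sum of the four sub-scores", {
  expect_equal(lifestyle_score(0, 0, 0, 0), 0)
  expect_equal(lifestyle_score(5, 6, 4, 6), 21)
  expect_equal(lifestyle_score(20, 16, 15, 15), 66)
  expect_true(is.na(lifestyle_score(5, NA, 4, 6)))
  expect_error(lifestyle_score(-1, 0, 0, 0), ">= 0")
})

test_that("smoking-excluded LS variant differs from the full LS by exactly the smoking sub-score", {
  expect_equal(ls_excluding_smoking(5, 6, 6), 17)
  expect_equal(ls_excluding_smoking(0, 0, 0), 0)
  set.seed(1)
  d <- sample(0:20, 50, TRUE); p <- sample(0:16, 50, TRUE)
  s <- sample(0:15, 50, TRUE); a <- sample(0:15, 50, TRUE)
  expect_equal(lifestyle_score(d, p, s, a) - ls_excluding_smoking(d, p, a), s)
})

test_that("alcohol banding penalizes only intake above the sex-specific threshold", {
  expect_equal(as.character(alcohol_subscore_band(10.0, "female")), "not_penalized")
  expect_equal(as.character(alcohol_subscore_band(20.1, "male")), "penalized")
  expect_equal(as.character(alcohol_subscore_band(0, "male")), "not_penalized")
  expect_equal(as.character(alcohol_subscore_band(10.1, "female")), "penalized")
  expect_equal(as.character(alcohol_subscore_band(20.0, "male")), "not_penalized")
  expect_error(alcohol_subscore_band(-1, "male"), ">= 0")
})

test_that("CONUT spans 0-12 with the canonical band assignments", {
  expect_equal(conut_score(45, 5.0, 1.8), 0L)
  expect_equal(conut_score(24, 2.0, 0.5), 12L)
  expect_equal(conut_score(45, 3.8, 1.8), 1L)
  # healthy-side band edges score the healthier band
  expect_equal(conut_score(35, 4.65, 1.6), 0L)
  expect_equal(conut_score(34.9, 4.64, 1.59), 2L + 1L + 1L)
})

test_that("CONUT equals an independent brute-force band lookup on 1000 random records", {
  set.seed(42)
  alb <- runif(1000, 20, 55)
  cho <- runif(1000, 1.5, 8)
  lym <- runif(1000, 0.2, 4)
  got <- suppressWarnings(conut_score(alb, cho, lym))
  want <- mapply(oracle_conut, alb, cho, lym)
  expect_identical(got, as.integer(want))
  expect_true(all(got >= 0 & got <= 12))
})

test_that("CONUT is monotonically non-increasing in each lab", {
  set.seed(7)
  for (i in 1:200) {
    alb <- runif(1, 20, 55); cho <- runif(1, 1.5, 8); lym <- runif(1, 0.2, 4)
    base <- suppressWarnings(conut_score(alb, cho, lym))
    eps <- runif(1, 0.01, 5)
    expect_lte(suppressWarnings(conut_score(alb + eps, cho, lym)), base)
    expect_lte(suppressWarnings(conut_score(alb, cho + eps, lym)), base)
    expect_lte(suppressWarnings(conut_score(alb, cho, lym + eps)), base)
  }
})

test_that("CONUT risk groups follow the 0 / 1-2 / >=3 categorisation", {
  expect_equal(as.character(conut_group(c(0, 1, 2, 3, 12))),
               c("low", "moderate", "moderate", "high", "high"))
  expect_error(conut_group(13), "\\[0, 12\\]")
  expect_error(conut_group(-1), "\\[0, 12\\]")
})

test_that("PNI and NRI match direct formula evaluation", {
  expect_equal(pni_score(45.8, 1.88), 55.2, tolerance = 1e-12)
  expect_equal(suppressWarnings(pni_score(0, 0)), 0)
  expect_equal(suppressWarnings(pni_score(56.35, 0)), 56.35)
  expect_equal(nri_score(40, 65, 65), 101.26, tolerance = 1e-12)
  expect_equal(nri_score(0, 0, 65), 0)
  expect_equal(nri_score(45.8, 80.6, 65), 1.489 * 45.8 + 41.7 * 80.6 / 65,
               tolerance = 1e-12)
  expect_error(nri_score(40, 65, 0), "> 0")

  set.seed(8)
  alb <- runif(1000, 25, 55); lym <- runif(1000, 0.2, 4)
  wt <- runif(1000, 45, 130); iw <- runif(1000, 45, 80)
  expect_equal(pni_score(alb, lym), alb + 5 * lym, tolerance = 1e-9)
  expect_equal(nri_score(alb, wt, iw), 1.489 * alb + 41.7 * wt / iw,
               tolerance = 1e-9)
})

test_that("PNI/NRI are strictly increasing in their inputs", {
  expect_gt(pni_score(46, 1.9), pni_score(45.9, 1.9))
  expect_gt(pni_score(46, 2.0), pni_score(46, 1.9))
  expect_gt(nri_score(46, 80, 65), nri_score(45.9, 80, 65))
  expect_gt(nri_score(46, 81, 65), nri_score(46, 80, 65))
})

test_that("Lorenz ideal weight follows the sex-specific formula and flags short heights", {
  expect_equal(suppressWarnings(lorenz_ideal_weight(150, "male")), 50)
  expect_equal(lorenz_ideal_weight(170, "male"), 65)
  expect_equal(lorenz_ideal_weight(170, "female"), 62)
  expect_warning(lorenz_ideal_weight(148, "female"), "150")
  expect_error(lorenz_ideal_weight(0, "male"), "> 0")
})

test_that("albumin unit gate flags g/dL-magnitude input", {
  expect_warning(pni_score(4.6, 1.8), "g/dL")
  expect_silent(pni_score(46, 1.8))
})

test_that("Framingham categories use the 5/10/20 percent boundaries", {
  expect_equal(as.character(framingham_category(c(4.9, 5, 9.9, 10, 15, 20, 20.1, 25))),
               c("low", "low_moderate", "low_moderate", "moderate_high",
                 "moderate_high", "moderate_high", "high", "high"))
  expect_error(framingham_category(101), "\\[0, 100\\]")
})

test_that("Framingham risk reproduces hand lookups in the shipped point table", {
  # 40-year-old male, all factors in the reference bands, nonsmoker,
  # nondiabetic: points = 1 (age) + 0 (TC 160-199) + 0 (HDL 45-49) + 0 (BP
  # normal) = 1 -> 3% in the male TC sheet
  r <- framingham_risk(age = 40, sex = "male", total_cholesterol = 180 / 38.67,
                       hdl = 46 / 38.67, systolic_bp = 124, diastolic_bp = 81,
                       diabetes = FALSE, smoker = FALSE)
  expect_equal(r, 3)
  # 55-year-old diabetic smoking female with low HDL and stage-I BP:
  # 7 (age) + 1 (TC 200-239) + 2 (HDL 35-44) + 2 (BP stage I) + 4 + 2 = 18
  # -> clamped to the sheet maximum row (>= 17 -> 27%)
  r2 <- framingham_risk(age = 55, sex = "female", total_cholesterol = 210 / 38.67,
                        hdl = 40 / 38.67, systolic_bp = 145, diastolic_bp = 92,
                        diabetes = TRUE, smoker = TRUE)
  expect_equal(r2, 27)
  # identical records give identical risk; missing input gives NA
  expect_equal(r, framingham_risk(40, "male", 180 / 38.67, 46 / 38.67,
                                  systolic_bp = 124, diastolic_bp = 81,
                                  diabetes = FALSE, smoker = FALSE))
  expect_true(is.na(framingham_risk(40, "male", NA, 46 / 38.67,
                                    systolic_bp = 124, diastolic_bp = 81,
                                    diabetes = FALSE, smoker = FALSE)))
})

test_that("score_cohort populates the full panel and propagates missingness per score", {
  cohort <- generate_cohort(test_config(n = 120))
  scored <- suppressWarnings(score_cohort(cohort))
  expect_equal(nrow(scored), 120)
  expect_true(all(c("ls", "ls_tercile", "conut", "conut_group", "pni",
                    "pni_group", "nri", "nri_group", "framingham_risk",
                    "framingham_category") %in% names(scored)))
  expect_false(any(is.na(scored$ls)))
  expect_equal(scored$id, cohort$id) # order preserved

  # knock out lymphocytes for one participant: CONUT/PNI null, LS/NRI kept
  cohort$lymphocytes[5] <- NA
  s2 <- suppressWarnings(score_cohort(cohort))
  expect_true(is.na(s2$conut[5]) && is.na(s2$pni[5]))
  expect_false(is.na(s2$nri[5]) || is.na(s2$ls[5]))
  # labels stay consistent with values under the active schemes
  ok <- !is.na(s2$pni)
  expect_equal(s2$pni_group[ok], pni_group(s2$pni[ok]))
})
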