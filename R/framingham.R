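#' Framingham categorical point tables (Wilson 1998)
#'
#' The sex-specific score sheets of the categorical Framingham 10-year
#' coronary heart disease model: points for age band, total- or
#' LDL-cholesterol band, HDL band, blood-pressure category, diabetes and
#' smoking, plus the point-total to percent-risk lookup. Shipped as plain
#' tables so the coefficient set in use is inspectable and replaceable.
#'
#' @return A named list of lookup tables (see source for layout).
#' @export
framingham_points <- function() {
  list(
    # upper thresholds separating the age bands 30-34 ... 70-74
    age_breaks = seq(35, 70, by = 5),
    age = list(male = c(-1, 0, 1, 2, 3, 4, 5, 6, 7),
               female = c(-9, -4, 0, 3, 6, 7, 8, 8, 8)),
    # total cholesterol, mg/dL: <160, 160-199, 200-239, 240-279, >=280
    tc_breaks = c(160, 200, 240, 280),
    tc = list(male = c(-3, 0, 1, 2, 3), female = c(-2, 0, 1, 1, 3)),
    # LDL cholesterol, mg/dL: <100, 100-129, 130-159, 160-189, >=190
    ldl_breaks = c(100, 130, 160, 190),
    ldl = list(male = c(-3, 0, 0, 1, 2), female = c(-2, 0, 0, 2, 2)),
    # HDL, mg/dL: <35, 35-44, 45-49, 50-59, >=60 (TC and LDL sheets differ)
    hdl_breaks = c(35, 45, 50, 60),
    hdl_tc = list(male = c(2, 1, 0, 0, -2), female = c(5, 2, 1, 0, -3)),
    hdl_ldl = list(male = c(2, 1, 0, 0, -1), female = c(5, 2, 1, 0, -2)),
    # blood pressure category: optimal / normal / high-normal / stage I /
    # stage II-IV, from the higher of the systolic and diastolic categories
    sbp_breaks = c(120, 130, 140, 160),
    dbp_breaks = c(80, 85, 90, 100),
    bp = list(male = c(0, 0, 1, 2, 3), female = c(-3, 0, 0, 2, 3)),
    diabetes = list(male = 2, female = 4),
    smoker = list(male = 2, female = 2),
    # point total -> 10-year CHD risk (%), clamped outside the printed range
    risk_tc = list(
      male = list(points = -1:14,
                  risk = c(2, 3, 3, 4, 5, 7, 8, 10, 13, 16, 20, 25, 31, 37, 45, 53)),
      female = list(points = -2:17,
                    risk = c(1, 2, 2, 2, 3, 3, 4, 4, 5, 6, 7, 8, 10, 11, 13, 15,
                             18, 20, 24, 27))
    ),
    risk_ldl = list(
      male = list(points = -3:14,
                  risk = c(1, 2, 2, 3, 4, 4, 6, 7, 9, 11, 14, 18, 22, 27, 33, 40,
                           47, 56)),
      female = list(points = -2:17,
                    risk = c(1, 2, 2, 2, 3, 3, 4, 5, 6, 7, 8, 9, 11, 13, 15, 17,
                             20, 24, 27, 32))
    )
  )
}

lookup_by_sex <- function(value, breaks, pts, sex) {
  idx <- findInterval(value, breaks) + 1L
  out <- rep(NA_real_, length(idx))
  male <- sex == "male"
  out[male] <- pts$male[idx[male]]
  out[!male] <- pts$female[idx[!male]]
  out
}

#' Framingham 10-year coronary heart disease risk
#'
#' Categorical point-table Framingham risk: age, sex, total (or LDL)
#' cholesterol, HDL, blood-pressure category, diabetes and smoking status
#' are each converted to points; the point total maps to a tabulated percent
#' risk. Lipid inputs are in mmol/L and converted to mg/dL internally
#' (x 38.67). Ages outside the tabulated 30-74 range are clamped to the
#' nearest band, and point totals outside the printed lookup are clamped to
#' its ends.
#'
#' @param age age in years.
#' @param sex `"male"` or `"female"`.
#' @param total_cholesterol,hdl,ldl lipids in mmol/L (`ldl` only used in
#'   `mode = "ldl"`).
#' @param systolic_bp,diastolic_bp blood pressure in mmHg.
#' @param diabetes,smoker logicals.
#' @param mode cholesterol sheet to use: `"tc"` (default) or `"ldl"`.
#' @param tables point tables, see [framingham_points()].
#' @return Numeric 10-year CHD risk in percent; `NA` where any required
#'   input is missing.
#' @export
framingham_risk <- function(age, sex, total_cholesterol, hdl, ldl = NA_real_,
                            systolic_bp, diastolic_bp, diabetes, smoker,
                            mode = c("tc", "ldl"),
                            tables = framingham_points()) {
  mode <- match.arg(mode)
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female", NA))) {
    abort("`sex` must be 'male' or 'female'")
  }
  age_cl <- pmin(pmax(age, 30), 74)
  pts <- lookup_by_sex(age_cl, tables$age_breaks, tables$age, sex)
  if (mode == "tc") {
    pts <- pts + lookup_by_sex(mmol_to_mgdl(total_cholesterol),
                               tables$tc_breaks, tables$tc, sex)
    pts <- pts + lookup_by_sex(mmol_to_mgdl(hdl), tables$hdl_breaks,
                               tables$hdl_tc, sex)
    risk_table <- tables$risk_tc
  } else {
    pts <- pts + lookup_by_sex(mmol_to_mgdl(ldl), tables$ldl_breaks,
                               tables$ldl, sex)
    pts <- pts + lookup_by_sex(mmol_to_mgdl(hdl), tables$hdl_breaks,
                               tables$hdl_ldl, sex)
    risk_table <- tables$risk_ldl
  }
  bp_cat <- pmax(
    findInterval(systolic_bp, tables$sbp_breaks),
    findInterval(diastolic_bp, tables$dbp_breaks)
  ) + 1L
  bp_pts <- rep(NA_real_, length(bp_cat))
  male <- sex == "male"
  bp_pts[male] <- tables$bp$male[bp_cat[male]]
  bp_pts[!male] <- tables$bp$female[bp_cat[!male]]
  pts <- pts + bp_pts
  pts <- pts +
    ifelse(male, tables$diabetes$male, tables$diabetes$female) * as.numeric(diabetes) +
    ifelse(male, tables$smoker$male, tables$smoker$female) * as.numeric(smoker)

  out <- rep(NA_real_, length(pts))
  for (s in c("male", "female")) {
    sel <- !is.na(sex) & sex == s & !is.na(pts)
    if (!any(sel)) next
    tab <- risk_table[[s]]
    p <- pmin(pmax(pts[sel], min(tab$points)), max(tab$points))
    out[sel] <- tab$risk[match(p, tab$points)]
  }
  out
}
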