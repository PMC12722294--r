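#' SD of a paired difference from the per-wave SDs
#'
#' Independence approximation used in the longitudinal lipid table:
#' `SD_diff ~ sqrt(SD_baseline^2 + SD_followup^2)`.
#'
#' @param sd_base,sd_follow per-wave standard deviations (>= 0).
#' @return Numeric approximate SD of the baseline-minus-follow-up
#'   difference.
#' @examples
#' sd_of_difference(1.05, 1.22) # 1.61
#' @export
sd_of_difference <- function(sd_base, sd_follow) {
  if (any(sd_base < 0, na.rm = TRUE) || any(sd_follow < 0, na.rm = TRUE)) {
    abort("standard deviations must be >= 0")
  }
  sqrt(sd_base^2 + sd_follow^2)
}

# Wilcoxon signed-rank test with Pratt handling of zero differences:
# zeros are ranked with everything else, then their rank-sum is removed from
# the null mean/variance. Normal approximation with tie correction; small
# samples without zeros/ties fall back to the exact distribution.
wilcoxon_signed_rank <- function(diff, exact_below = 25) {
  diff <- diff[!is.na(diff)]
  n <- length(diff)
  if (n < 1) return(NA_real_)
  if (all(diff == 0)) {
    warn("all paired differences are zero; p = 1")
    return(1)
  }
  n0 <- sum(diff == 0)
  if (n < exact_below && n0 == 0 && !any(duplicated(abs(diff)))) {
    return(wilcox.test(diff, exact = TRUE)$p.value)
  }
  r <- rank(abs(diff))
  w_pos <- sum(r[diff > 0])
  mu <- n * (n + 1) / 4 - n0 * (n0 + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    n0 * (n0 + 1) * (2 * n0 + 1) / 24 -
    sum(ties^3 - ties) / 48
  if (sigma2 <= 0) return(1)
  z <- (w_pos - mu) / sqrt(sigma2)
  2 * pnorm(-abs(z))
}

followup_col <- function(var) paste0(var, "_followup")

#' Paired baseline-to-follow-up lipid changes by lifestyle tercile
#'
#' Restricted to participants with both waves present for a variable
#' (paired-complete). The difference is `baseline - followup`, so positive
#' means indicate a decline over time. The reported `sd_diff_approx` uses
#' the [sd_of_difference()] combination of the per-wave SDs (alongside the
#' exact empirical SD of the per-person differences), and the within-group
#' change is tested with a paired Wilcoxon signed-rank test (Pratt zero
#' handling; exact for small n).
#'
#' @param data a scored cohort carrying `<var>` and `<var>_followup`
#'   columns.
#' @param vars baseline column names of the paired lipids.
#' @param by grouping column (default the lifestyle tercile).
#' @return A tibble with one row per group x variable: n, per-wave mean/SD,
#'   `mean_diff`, `sd_diff`, `sd_diff_approx`, `p_value`. Strata with fewer
#'   than 2 pairs are reported as `NA` rows.
#' @export
paired_difference_summary <- function(data,
                                      vars = c("total_cholesterol", "hdl",
                                               "triglycerides"),
                                      by = "ls_tercile") {
  need <- c(by, vars, followup_col(vars))
  if (!all(need %in% names(data))) {
    abort(paste("missing columns:",
                paste(setdiff(need, names(data)), collapse = ", ")))
  }
  g <- if (is.factor(data[[by]])) data[[by]] else factor(data[[by]])
  map_dfr(vars, function(v) {
    base <- data[[v]]
    fol <- data[[followup_col(v)]]
    map_dfr(levels(g), function(lev) {
      sel <- !is.na(g) & g == lev & !is.na(base) & !is.na(fol)
      nn <- sum(sel)
      if (nn < 2) {
        return(tibble(variable = v, group = lev, n = nn,
                      mean_base = NA_real_, sd_base = NA_real_,
                      mean_follow = NA_real_, sd_follow = NA_real_,
                      mean_diff = NA_real_, sd_diff = NA_real_,
                      sd_diff_approx = NA_real_, p_value = NA_real_))
      }
      b <- base[sel]
      f <- fol[sel]
      d <- b - f
      tibble(
        variable = v, group = lev, n = nn,
        mean_base = mean(b), sd_base = sd(b),
        mean_follow = mean(f), sd_follow = sd(f),
        mean_diff = mean(d), sd_diff = sd(d),
        sd_diff_approx = sd_of_difference(sd(b), sd(f)),
        p_value = wilcoxon_signed_rank(d)
      )
    })
  })
}

#' Between-tercile comparison of per-person lipid changes
#'
#' Rank-sum tests comparing the distribution of per-person
#' baseline-minus-follow-up changes between each pair of groups
#' (T1 vs T2, T1 vs T3, T2 vs T3).
#'
#' @inheritParams paired_difference_summary
#' @return A tibble with `variable`, `comparison`, `p_value`; comparisons
#'   involving an empty (or singleton) group are `NA`.
#' @export
between_tercile_change_test <- function(data,
                                        vars = c("total_cholesterol", "hdl",
                                                 "triglycerides"),
                                        by = "ls_tercile") {
  need <- c(by, vars, followup_col(vars))
  if (!all(need %in% names(data))) {
    abort(paste("missing columns:",
                paste(setdiff(need, names(data)), collapse = ", ")))
  }
  g <- if (is.factor(data[[by]])) data[[by]] else factor(data[[by]])
  lev <- levels(g)
  if (length(lev) < 2) abort("need at least 2 groups to compare")
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  map_dfr(vars, function(v) {
    d <- data[[v]] - data[[followup_col(v)]]
    map_dfr(pairs, function(p) {
      x <- d[!is.na(g) & g == p[1] & !is.na(d)]
      y <- d[!is.na(g) & g == p[2] & !is.na(d)]
      pv <- if (length(x) < 2 || length(y) < 2) {
        NA_real_
      } else {
        suppressWarnings(wilcox.test(x, y)$p.value)
      }
      tibble(variable = v, comparison = paste(p[1], "vs", p[2]),
             p_value = pv)
    })
  })
}
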