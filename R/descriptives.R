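#' Cross-tabulate two score groupings
#'
#' Counts and row percentages for the joint distribution of two categorical
#' score columns (e.g. lifestyle-score terciles against CONUT risk groups).
#' Pairs with a missing label on either side are dropped and counted.
#'
#' @param data a data frame.
#' @param rows,cols column names (strings) of the row and column groupings.
#' @return An object of class `ls_crosstab`: counts matrix, row-percentage
#'   matrix (denominator = non-missing row total), and the number of
#'   dropped incomplete pairs. `tidy()` returns the long form.
#' @examples
#' d <- data.frame(a = c("x", "x", "y"), b = c("u", "v", "u"))
#' cross_tabulate(d, "a", "b")
#' @export
cross_tabulate <- function(data, rows, cols) {
  if (!all(c(rows, cols) %in% names(data))) {
    abort("`rows` and `cols` must name columns of `data`")
  }
  r <- data[[rows]]
  cl <- data[[cols]]
  keep <- !is.na(r) & !is.na(cl)
  if (!any(keep)) abort("no complete pairs to tabulate")
  counts <- table(row = r[keep], col = cl[keep])
  counts <- unclass(counts)
  names(dimnames(counts)) <- c(rows, cols)
  row_pct <- 100 * sweep(counts, 1, pmax(rowSums(counts), 1), "/")
  structure(
    list(counts = counts, row_pct = row_pct,
         n = sum(counts), n_dropped = sum(!keep),
         row_var = rows, col_var = cols),
    class = "ls_crosstab"
  )
}

#' @export
print.ls_crosstab <- function(x, digits = 1, ...) {
  cat("<ls_crosstab> ", x$row_var, " x ", x$col_var,
      "  (n = ", x$n, ", dropped = ", x$n_dropped, ")\n", sep = "")
  disp <- matrix(
    paste0(x$counts, " (", formatC(x$row_pct, format = "f", digits = digits),
           "%)"),
    nrow = nrow(x$counts), dimnames = dimnames(x$counts)
  )
  print(disp, quote = FALSE)
  invisible(x)
}

#' @export
tidy.ls_crosstab <- function(x, ...) {
  df <- as.data.frame.table(as.table(x$counts), responseName = "count")
  df$row_pct <- as.vector(x$row_pct) # both are column-major
  names(df)[1:2] <- c(x$row_var, x$col_var)
  as_tibble(df)
}

#' Pearson chi-square test of independence
#'
#' Chi-square test on a contingency table without continuity correction,
#' `df = (r-1)(c-1)`. Warns when any expected cell count is below 5.
#'
#' @param table an [cross_tabulate()] result, matrix, or table of counts.
#' @return A tibble with `statistic`, `df`, `p_value`.
#' @export
chi_square_independence <- function(table) {
  counts <- if (inherits(table, "ls_crosstab")) table$counts else as.matrix(table)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("zero row or column marginal; drop empty categories first")
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected < 5)) {
    warn("some expected cell counts are below 5; chi-square may be inaccurate")
  }
  res <- suppressWarnings(chisq.test(counts, correct = FALSE))
  tibble(statistic = unname(res$statistic),
         df = unname(res$parameter),
         p_value = unname(res$p.value))
}

#' Covariate-adjusted group comparison (ANCOVA with Tukey post-hoc)
#'
#' Ordinary least squares of the outcome on the group factor plus
#' covariates; the group effect is tested with a type-II F test and
#' pairwise differences of the adjusted (estimated marginal) means are
#' compared with Tukey-adjusted p-values.
#'
#' @param data a data frame.
#' @param outcome,group column names (strings); `group` is coerced to factor.
#' @param covariates character vector of adjustment columns (default age
#'   and sex; lipid outcomes are conventionally additionally adjusted for
#'   BMI).
#' @return An object of class `ls_ancova` with the fitted `lm`, an overall
#'   tibble (`statistic`, `df`, `p_value`) and a `pairwise` tibble of Tukey
#'   contrasts. `glance()`/`tidy()` return the overall test and the
#'   contrasts.
#' @export
adjusted_group_comparison <- function(data, outcome, group,
                                      covariates = c("age", "sex")) {
  cols <- c(outcome, group, covariates)
  if (!all(cols %in% names(data))) {
    abort(paste("missing columns:",
                paste(setdiff(cols, names(data)), collapse = ", ")))
  }
  d <- data[complete.cases(data[cols]), cols, drop = FALSE]
  d[[group]] <- factor(d[[group]])
  d[[group]] <- droplevels(d[[group]])
  if (nlevels(d[[group]]) < 2 || any(table(d[[group]]) < 2)) {
    abort("need >= 2 groups with >= 2 observations each")
  }
  fml <- as.formula(paste(outcome, "~", paste(c(group, covariates),
                                              collapse = " + ")))
  fit <- lm(fml, data = d)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste("singular design; aliased terms:", paste(bad, collapse = ", ")))
  }
  an <- car::Anova(fit, type = 2)
  i <- match(group, rownames(an))
  emm <- emmeans::emmeans(fit, specs = group)
  pw <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                        adjust = "tukey"))
  structure(
    list(
      fit = fit,
      overall = tibble(statistic = an[i, "F value"],
                       df = an[i, "Df"], df_resid = an["Residuals", "Df"],
                       p_value = an[i, "Pr(>F)"]),
      emmeans = as.data.frame(emm),
      pairwise = tibble(contrast = as.character(pw$contrast),
                        estimate = pw$estimate, se = pw$SE,
                        p_value = pw$p.value)
    ),
    class = "ls_ancova"
  )
}

#' @export
glance.ls_ancova <- function(x, ...) x$overall

#' @export
tidy.ls_ancova <- function(x, ...) x$pairwise

#' @export
print.ls_ancova <- function(x, ...) {
  cat("<ls_ancova> group F =", formatC(x$overall$statistic, digits = 4),
      " p =", format.pval(x$overall$p_value, digits = 3), "\n")
  print(x$pairwise)
  invisible(x)
}

#' Rank-based group comparison
#'
#' Kruskal-Wallis test across three or more groups, Wilcoxon rank-sum for
#' two - the convention for skewed outcomes such as triglycerides.
#'
#' @inheritParams adjusted_group_comparison
#' @return A tibble with `method`, `statistic`, `df` (KW only), `p_value`.
#' @export
rank_test <- function(data, outcome, group) {
  d <- data[complete.cases(data[c(outcome, group)]), c(outcome, group)]
  g <- droplevels(factor(d[[group]]))
  y <- d[[outcome]]
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    abort("need >= 2 groups with >= 2 observations each")
  }
  if (length(unique(y)) == 1) {
    warn("constant outcome; returning p = 1")
    return(tibble(method = "constant", statistic = NA_real_,
                  df = NA_real_, p_value = 1))
  }
  if (nlevels(g) == 2) {
    res <- wilcox.test(y ~ g)
    tibble(method = "wilcoxon_rank_sum", statistic = unname(res$statistic),
           df = NA_real_, p_value = res$p.value)
  } else {
    res <- kruskal.test(y ~ g)
    tibble(method = "kruskal_wallis", statistic = unname(res$statistic),
           df = unname(res$parameter), p_value = res$p.value)
  }
}

cor_row <- function(x, y, method, xname, yname) {
  ok <- complete.cases(x, y)
  if (sum(ok) < 3) {
    warn(paste0("fewer than 3 complete pairs for ", xname, " vs ", yname))
    return(tibble(x = xname, y = yname, method = method,
                  estimate = NA_real_, p_value = NA_real_, n = sum(ok)))
  }
  res <- suppressWarnings(cor.test(x[ok], y[ok], method = method))
  tibble(x = xname, y = yname, method = method,
         estimate = unname(res$estimate), p_value = res$p.value, n = sum(ok))
}

#' Correlations between the lifestyle score, its components and other scores
#'
#' Reproduces the correlation surface of the analysis: Spearman and Pearson
#' correlations of the Framingham risk with the full LS, with the
#' smoking-excluded LS variant and with each sub-score, plus Kendall's tau
#' (appropriate for the heavily tied discrete sub-scores) between the diet
#' and smoking sub-scores and each malnutrition index.
#'
#' @param data a scored cohort (see [score_cohort()]).
#' @return A tibble with one row per pair x method: `x`, `y`, `method`,
#'   `estimate`, `p_value`, `n`.
#' @export
score_correlations <- function(data) {
  need <- c("ls", "ls_no_smoking", "framingham_risk", "diet_subscore",
            "pa_subscore", "smoking_subscore", "alcohol_subscore",
            "conut", "pni", "nri")
  if (!all(need %in% names(data))) {
    abort(paste("missing columns:",
                paste(setdiff(need, names(data)), collapse = ", ")))
  }
  fs <- data$framingham_risk
  rows <- list()
  for (m in c("spearman", "pearson")) {
    rows <- c(rows, list(
      cor_row(data$ls, fs, m, "ls", "framingham_risk"),
      cor_row(data$ls_no_smoking, fs, m, "ls_no_smoking", "framingham_risk"),
      cor_row(data$diet_subscore, fs, m, "diet_subscore", "framingham_risk"),
      cor_row(data$pa_subscore, fs, m, "pa_subscore", "framingham_risk"),
      cor_row(data$smoking_subscore, fs, m, "smoking_subscore",
              "framingham_risk"),
      cor_row(data$alcohol_subscore, fs, m, "alcohol_subscore",
              "framingham_risk")
    ))
  }
  for (sub in c("diet_subscore", "smoking_subscore")) {
    for (sc in c("conut", "pni", "nri")) {
      rows <- c(rows, list(cor_row(data[[sub]], data[[sc]], "kendall",
                                   sub, sc)))
    }
  }
  bind_rows(rows)
}
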