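#' Kaplan-Meier curves by score group
#'
#' Product-limit survival estimates per group with a log-rank test across
#' groups. With no events anywhere the curves are flat and the log-rank p is
#' returned as `NA` with a warning.
#'
#' @param data cohort with survival columns.
#' @param group optional grouping column name (`NULL` = one overall curve).
#' @param time,event survival column names (months; logical/0-1 event).
#' @return An object of class `ls_km`: `table` (tibble with `group`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`, confidence bounds) and
#'   `logrank` (tibble `statistic`, `df`, `p_value`). Supports `autoplot()`.
#' @export
km_curves <- function(data, group = NULL, time = "survival_months",
                      event = "event") {
  if (!all(c(time, event) %in% names(data))) {
    abort("survival columns not found")
  }
  d <- data[complete.cases(data[c(time, event, group)]),
            c(time, event, group), drop = FALSE]
  names(d)[1:2] <- c(".time", ".event")
  d$.event <- as.integer(d$.event)
  if (any(d$.time < 0)) abort("survival times must be >= 0")
  if (!is.null(group)) {
    d$.group <- droplevels(factor(d[[group]]))
    fit <- survfit(Surv(.time, .event) ~ .group, data = d)
    groups <- if (is.null(fit$strata)) levels(d$.group) else
      sub("^\\.group=", "", names(fit$strata))
    grp <- rep(groups, fit$strata %||% length(fit$time))
  } else {
    fit <- survfit(Surv(.time, .event) ~ 1, data = d)
    grp <- rep("all", length(fit$time))
  }
  tab <- tibble(
    group = grp, time = fit$time, n_risk = fit$n.risk,
    n_event = fit$n.event, n_censor = fit$n.censor,
    survival = fit$surv, conf_low = fit$lower, conf_high = fit$upper
  )
  logrank <- tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_)
  if (sum(d$.event) == 0) {
    warn("no events; log-rank test undefined")
  } else if (!is.null(group) && nlevels(d$.group) > 1) {
    lr <- survdiff(Surv(.time, .event) ~ .group, data = d)
    df <- length(lr$n) - 1
    logrank <- tibble(statistic = lr$chisq, df = df,
                      p_value = pchisq(lr$chisq, df, lower.tail = FALSE))
  }
  structure(list(table = tab, logrank = logrank, fit = fit,
                 group_var = group %||% "all"),
            class = "ls_km")
}

#' @export
print.ls_km <- function(x, ...) {
  cat("<ls_km> product-limit estimates by", x$group_var, "\n")
  if (is.finite(x$logrank$p_value)) {
    cat("  log-rank chi-square =", formatC(x$logrank$statistic, digits = 4),
        "df =", x$logrank$df,
        "p =", format.pval(x$logrank$p_value, digits = 3), "\n")
  }
  invisible(x)
}

#' @export
tidy.ls_km <- function(x, ...) x$table

build_surv_formula <- function(terms, time, event) {
  as.formula(paste0("Surv(", time, ", ", event, ") ~ ",
                    paste(terms, collapse = " + ")))
}

prepare_cox_data <- function(data, vars, time, event, ref_high) {
  cols <- unique(c(time, event, vars))
  if (!all(cols %in% names(data))) {
    abort(paste("missing columns:",
                paste(setdiff(cols, names(data)), collapse = ", ")))
  }
  d <- data[complete.cases(data[cols]), cols, drop = FALSE]
  d[[event]] <- as.integer(d[[event]])
  if (sum(d[[event]]) < 1) abort("need at least one event")
  for (v in vars) {
    if (is.character(d[[v]])) d[[v]] <- factor(d[[v]])
    if (is.factor(d[[v]])) {
      d[[v]] <- droplevels(d[[v]])
      lv <- levels(d[[v]])
      # tercile-coded scores use the unfavourable (3rd/high) group as the
      # reference, matching the reporting convention
      if (ref_high && length(lv) == 3 &&
          (all(lv == c("T1", "T2", "T3")) ||
             all(lv == c("low", "moderate", "high")))) {
        d[[v]] <- relevel(d[[v]], ref = lv[3])
      }
    } else if (any(!is.finite(d[[v]]))) {
      abort(paste0("non-finite values in covariate `", v, "`"))
    }
  }
  d
}

#' Cox proportional-hazards fit with tidy output
#'
#' Partial-likelihood Cox regression (Efron tie handling - event times on a
#' monthly grid are heavily tied) for a score of interest plus adjustment
#' covariates. Factor covariates with levels `T1/T2/T3` or
#' `low/moderate/high` are recoded with the 3rd/high group as reference, so
#' reported tercile hazard ratios are "versus the unfavourable group".
#' Schoenfeld proportionality tests are attached.
#'
#' @param data cohort data frame.
#' @param terms character vector of covariate column names; the first is
#'   conventionally the score of interest.
#' @param time,event survival column names.
#' @param ref_high recode 3-level score factors to the high/unfavourable
#'   reference (default TRUE). Set FALSE to keep the natural first-level
#'   reference (e.g. T1).
#' @return An object of class `ls_cox`: the `survival::coxph` fit plus tidy
#'   coefficient and diagnostic tables. `tidy()` gives terms with hazard
#'   ratios, Wald 95% CIs and p-values; `glance()` gives n, events, partial
#'   log-likelihood and the global Schoenfeld p.
#' @export
cox_fit <- function(data, terms, time = "survival_months", event = "event",
                    ref_high = TRUE) {
  d <- prepare_cox_data(data, terms, time, event, ref_high)
  fml <- build_surv_formula(terms, time, event)
  fit <- coxph(fml, data = d, ties = "efron", model = TRUE)
  if (!is.null(fit$info) && isTRUE(fit$info$flag > 0)) {
    abort("Cox fit did not converge")
  }
  beta <- coef(fit)
  if (any(abs(beta) > 10)) {
    warn("very large coefficient; possible complete separation")
  }
  se <- sqrt(diag(fit$var))
  ci <- confint(fit)
  coefs <- tibble(
    term = names(beta), beta = unname(beta), se = unname(se),
    hr = exp(unname(beta)),
    conf_low = exp(ci[, 1]), conf_high = exp(ci[, 2]),
    p_value = 2 * pnorm(-abs(unname(beta) / unname(se)))
  )
  sch <- tryCatch(schoenfeld_table(fit), error = function(e) NULL)
  structure(
    list(fit = fit, coefs = coefs, schoenfeld = sch,
         n = fit$n, n_events = fit$nevent,
         loglik = fit$loglik[length(fit$loglik)]),
    class = "ls_cox"
  )
}

schoenfeld_table <- function(fit) {
  z <- cox.zph(fit)
  tab <- as.data.frame(z$table)
  tibble(term = rownames(tab), chisq = tab$chisq, df = tab$df,
         p_value = tab$p)
}

#' Schoenfeld proportional-hazards diagnostics
#'
#' Scaled Schoenfeld residual tests of the proportional-hazards assumption,
#' per covariate and globally. With fewer than two events the test is not
#' computable and `NULL` is returned with a warning.
#'
#' @param fit an [cox_fit()] result.
#' @return A tibble with `term` (including `GLOBAL`), `chisq`, `df`,
#'   `p_value`, or `NULL`.
#' @export
schoenfeld_check <- function(fit) {
  stopifnot(inherits(fit, "ls_cox"))
  if (fit$n_events < 2) {
    warn("fewer than 2 events; Schoenfeld test not computable")
    return(NULL)
  }
  fit$schoenfeld %||% {
    warn("Schoenfeld test could not be computed for this fit")
    NULL
  }
}

#' @export
tidy.ls_cox <- function(x, ...) x$coefs

#' @export
glance.ls_cox <- function(x, ...) {
  global_p <- NA_real_
  if (!is.null(x$schoenfeld)) {
    global_p <- x$schoenfeld$p_value[x$schoenfeld$term == "GLOBAL"]
  }
  tibble(n = x$n, n_events = x$n_events, loglik = x$loglik,
         schoenfeld_global_p = global_p)
}

#' @export
print.ls_cox <- function(x, ...) {
  cat("<ls_cox> n =", x$n, " events =", x$n_events, "\n")
  print(x$coefs)
  invisible(x)
}

#' Standardize a lifestyle score to z-scores
#'
#' Centres and scales over the analysis sample, so one unit equals one
#' sample SD of the score (one SD "less healthy" for scores where higher is
#' worse).
#'
#' @param ls numeric score values.
#' @return Numeric z-scores (sample mean 0, SD 1).
#' @export
standardize_ls <- function(ls) {
  m <- mean(ls, na.rm = TRUE)
  s <- sd(ls, na.rm = TRUE)
  if (!is.finite(s) || s == 0) abort("score SD must be positive")
  (ls - m) / s
}

#' Age-group effect modification of the lifestyle-score-mortality link
#'
#' Standardizes the lifestyle score over the analysis sample, then
#' (a) tests effect modification by age group (`<60`, `60-69`, `>=70`) with
#' a likelihood-ratio test of the multiplicative `LS_z x age group`
#' interaction (2 df) in Cox models adjusted for the given covariates;
#' (b) fits a per-stratum Cox model reporting the hazard ratio per 1-SD
#' worse lifestyle in each age group; and (c) within the oldest stratum,
#' fits tercile-coded hazard ratios against the healthiest tercile (T1).
#'
#' @param data a scored cohort (needs `ls`, `ls_tercile`, `age` plus
#'   survival and covariate columns).
#' @param covariates adjustment covariates (default sex and BMI; age acts
#'   through the grouping).
#' @param age_breaks the two inner age cut points (left-closed: 60 falls in
#'   `60-69`, 70 in `>=70`).
#' @param time,event survival column names.
#' @return An object of class `ls_age_interaction`: `lrt` (statistic, df,
#'   p), `strata` (per-age-group HR per SD with CI, n, events),
#'   `tercile_oldest` (T2/T3 vs T1 HRs in the `>=70` stratum), and the
#'   underlying fits. Strata without events are reported as `NA` rows.
#' @export
age_interaction_analysis <- function(data, covariates = c("sex", "bmi"),
                                     age_breaks = c(60, 70),
                                     time = "survival_months",
                                     event = "event") {
  need <- c("ls", "ls_tercile", "age", covariates, time, event)
  if (!all(need %in% names(data))) {
    abort(paste("missing columns:",
                paste(setdiff(need, names(data)), collapse = ", ")))
  }
  d <- data[complete.cases(data[need]), , drop = FALSE]
  d$ls_z <- standardize_ls(d$ls)
  d$age_group <- age_group_cut(d$age, age_breaks)
  d[[event]] <- as.integer(d[[event]])

  base_terms <- c("ls_z", "age_group", covariates)
  f0 <- build_surv_formula(base_terms, time, event)
  f1 <- build_surv_formula(c(base_terms, "ls_z:age_group"), time, event)
  fit0 <- coxph(f0, data = d, ties = "efron")
  fit1 <- coxph(f1, data = d, ties = "efron")
  lrt_stat <- 2 * (fit1$loglik[2] - fit0$loglik[2])
  lrt_df <- length(coef(fit1)) - length(coef(fit0))
  lrt <- tibble(statistic = lrt_stat, df = lrt_df,
                p_value = pchisq(lrt_stat, lrt_df, lower.tail = FALSE))

  strata <- map_dfr(levels(d$age_group), function(g) {
    sub <- d[d$age_group == g, , drop = FALSE]
    empty <- tibble(age_group = g, n = nrow(sub),
                    n_events = sum(sub[[event]]), hr = NA_real_,
                    conf_low = NA_real_, conf_high = NA_real_,
                    p_value = NA_real_)
    if (nrow(sub) < 2 || sum(sub[[event]]) < 1) return(empty)
    f <- tryCatch(
      cox_fit(sub, c("ls_z", covariates), time = time, event = event),
      error = function(e) NULL
    )
    if (is.null(f)) return(empty)
    row <- f$coefs[f$coefs$term == "ls_z", ]
    tibble(age_group = g, n = f$n, n_events = f$n_events, hr = row$hr,
           conf_low = row$conf_low, conf_high = row$conf_high,
           p_value = row$p_value)
  })

  oldest <- d[d$age_group == levels(d$age_group)[3], , drop = FALSE]
  tercile_oldest <- tibble(term = character(), hr = numeric(),
                           conf_low = numeric(), conf_high = numeric(),
                           p_value = numeric())
  fit_oldest <- NULL
  if (nrow(oldest) >= 2 && sum(oldest[[event]]) >= 1) {
    fit_oldest <- tryCatch(
      cox_fit(oldest, c("ls_tercile", covariates), time = time,
              event = event, ref_high = FALSE),
      error = function(e) NULL
    )
    if (!is.null(fit_oldest)) {
      tercile_oldest <- fit_oldest$coefs |>
        filter(grepl("^ls_tercile", .data$term)) |>
        select("term", "hr", "conf_low", "conf_high", "p_value")
    }
  }

  structure(
    list(lrt = lrt, strata = strata, tercile_oldest = tercile_oldest,
         fit_null = fit0, fit_interaction = fit1, fit_oldest = fit_oldest),
    class = "ls_age_interaction"
  )
}

#' @export
tidy.ls_age_interaction <- function(x, ...) x$strata

#' @export
glance.ls_age_interaction <- function(x, ...) x$lrt

#' @export
print.ls_age_interaction <- function(x, ...) {
  cat("<ls_age_interaction> LRT chi-square =",
      formatC(x$lrt$statistic, digits = 4), "df =", x$lrt$df,
      "p =", format.pval(x$lrt$p_value, digits = 3), "\n")
  print(x$strata)
  if (nrow(x$tercile_oldest)) {
    cat("Tercile HRs vs T1 in the oldest stratum:\n")
    print(x$tercile_oldest)
  }
  invisible(x)
}
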