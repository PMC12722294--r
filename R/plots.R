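#' Plot Kaplan-Meier curves
#'
#' Step survival curves per group on a monthly time axis.
#'
#' @param object an [km_curves()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ls_km <- function(object, ...) {
  tab <- object$table |>
    group_by(.data$group) |>
    group_modify(~ bind_rows(
      tibble(time = 0, survival = 1, conf_low = 1, conf_high = 1), .x
    )) |>
    ungroup()
  ggplot(tab, aes(x = .data$time, y = .data$survival,
                  colour = .data$group)) +
    geom_step() +
    coord_cartesian(ylim = c(min(tab$survival) * 0.98, 1)) +
    labs(x = "Months since baseline", y = "Survival probability",
         colour = object$group_var) +
    theme_minimal()
}

#' Forest plot of hazard ratios
#'
#' Hazard ratios with 95% confidence intervals on a log scale.
#'
#' @param object an [cox_fit()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ls_cox <- function(object, ...) {
  ggplot(object$coefs, aes(x = .data$hr, y = .data$term)) +
    geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$conf_low, xmax = .data$conf_high),
                   height = 0.2) +
    scale_x_log10() +
    labs(x = "Hazard ratio (95% CI, log scale)", y = NULL) +
    theme_minimal()
}

#' Forest plot of per-age-group lifestyle-score hazard ratios
#'
#' @param object an [age_interaction_analysis()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ls_age_interaction <- function(object, ...) {
  ggplot(object$strata, aes(x = .data$hr, y = .data$age_group)) +
    geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$conf_low, xmax = .data$conf_high),
                   height = 0.2) +
    scale_x_log10() +
    labs(x = "HR per 1-SD worse lifestyle (95% CI, log scale)",
         y = "Age group") +
    theme_minimal()
}

#' Score distributions by lifestyle tercile
#'
#' Boxplots of a score column stratified by lifestyle tercile.
#'
#' @param data a scored cohort.
#' @param score score column name (default Framingham risk).
#' @return A ggplot object.
#' @export
plot_score_by_tercile <- function(data, score = "framingham_risk") {
  ggplot(data[!is.na(data$ls_tercile), ],
         aes(x = .data$ls_tercile, y = .data[[score]])) +
    geom_boxplot(outlier.alpha = 0.3) +
    labs(x = "Lifestyle-score tercile", y = score) +
    theme_minimal()
}
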