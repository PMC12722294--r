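#' Read a cohort CSV
#'
#' Reads a one-row-per-participant cohort file with configurable delimiter
#' and decimal mark (German-style `;`-separated, comma-decimal files are
#' supported), validates the required columns, coerces types per the data
#' dictionary ([cohort_columns()]), applies unit plausibility gates (albumin
#' stored in g/L), and drops rows failing basic range checks with a message
#' reporting the count.
#'
#' @param path CSV file path.
#' @param delim field delimiter (default `","`).
#' @param decimal_mark decimal mark (default `"."`).
#' @param required columns that must be present.
#' @return A validated cohort tibble.
#' @export
read_cohort_csv <- function(path, delim = ",", decimal_mark = ".",
                            required = c("id", "sex", "age", "height",
                                         "weight", "albumin",
                                         "total_cholesterol", "hdl",
                                         "triglycerides", "lymphocytes")) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  data <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, trim_ws = TRUE,
    locale = readr::locale(decimal_mark = decimal_mark,
                           grouping_mark = ifelse(decimal_mark == ",", ".", ","))
  )
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    abort(paste("missing required columns:",
                paste(missing_cols, collapse = ", ")))
  }
  data$sex <- tolower(as.character(data$sex))
  bad_sex <- !data$sex %in% c("male", "female") & !is.na(data$sex)
  for (col in c("diabetes", "smoker", "event", "mace")) {
    if (col %in% names(data) && !is.logical(data[[col]])) {
      data[[col]] <- as.logical(data[[col]])
    }
  }
  bad <- bad_sex |
    (data$height <= 0 & !is.na(data$height)) |
    (data$weight <= 0 & !is.na(data$weight)) |
    (data$albumin < 0 & !is.na(data$albumin)) |
    (data$lymphocytes < 0 & !is.na(data$lymphocytes))
  if ("survival_months" %in% names(data)) {
    bad <- bad | (data$survival_months < 0 & !is.na(data$survival_months))
  }
  if (any(bad)) {
    inform(paste(sum(bad), "row(s) failed validation and were excluded"))
    data <- data[!bad, , drop = FALSE]
  }
  check_albumin_units(data$albumin)
  as_tibble(data)
}

#' Pipeline configuration
#'
#' @param input optional path to a cohort CSV; when `NULL` a synthetic
#'   cohort is generated from `sim`.
#' @param sim a [sim_config()] used when `input` is `NULL`.
#' @param out_dir output directory for the report bundle (created if
#'   needed); `NULL` skips file output.
#' @param seed seed driving all randomness (overrides `sim$seed`).
#' @param delim,decimal_mark CSV dialect for `input`.
#' @param covariates adjustment covariates for the Cox models.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, sim = sim_config(), out_dir = NULL,
                            seed = 1L, delim = ",", decimal_mark = ".",
                            covariates = c("age", "sex", "bmi")) {
  if (!is.null(input) && !file.exists(input)) {
    abort(paste("input file not found:", input))
  }
  structure(as.list(environment()), class = "pipeline_config")
}

write_stage <- function(x, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  readr::write_csv(x, file.path(out_dir, paste0(name, ".csv")))
}

#' Run the full analysis pipeline
#'
#' One-command replication of the whole analysis on synthetic or
#' user-supplied data: load or simulate the cohort, score it, produce the
#' grouped descriptive summary, the score-pair cross-tabs with chi-square
#' tests, the correlation report, the Cox fits (continuous and
#' tercile-coded for each score), the age-interaction analysis and the
#' paired longitudinal lipid report, then write each table as CSV plus a
#' manifest (seed, config hash, package version). Identical config + seed
#' reproduce identical numeric outputs.
#'
#' @param config a [pipeline_config()].
#' @return (Invisibly) a named list with every stage result and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- if (is.null(config$input)) {
    generate_cohort(config$sim, seed = config$seed)
  } else {
    read_cohort_csv(config$input, delim = config$delim,
                    decimal_mark = config$decimal_mark)
  }
  scored <- score_cohort(cohort)

  summary_tbl <- summarize_cohort(scored)
  crosstabs <- list(
    conut = cross_tabulate(scored, "ls_tercile", "conut_group"),
    pni = cross_tabulate(scored, "ls_tercile", "pni_group"),
    nri = cross_tabulate(scored, "ls_tercile", "nri_group")
  )
  chisq <- imap(crosstabs, ~ mutate(chi_square_independence(.x),
                                    pair = paste0("ls_tercile x ", .y))) |>
    bind_rows()
  correlations <- score_correlations(scored)

  cox_models <- NULL
  age_interaction <- NULL
  km <- NULL
  if (all(c("survival_months", "event") %in% names(scored)) &&
      sum(scored$event, na.rm = TRUE) > 0) {
    specs <- list(
      ls_continuous = "ls", ls_tercile = "ls_tercile",
      conut_continuous = "conut", conut_group = "conut_group",
      pni_continuous = "pni", pni_tercile = "pni_group",
      nri_continuous = "nri", nri_tercile = "nri_group"
    )
    cox_models <- imap(specs, function(score, nm) {
      fit <- cox_fit(scored, c(score, config$covariates))
      mutate(tidy(fit), model = nm, .before = 1)
    }) |> bind_rows()
    age_interaction <- age_interaction_analysis(scored)
    km <- km_curves(scored, "ls_tercile")
  }

  longitudinal <- NULL
  if (any(grepl("_followup$", names(scored)))) {
    longitudinal <- paired_difference_summary(scored)
    longitudinal_between <- between_tercile_change_test(scored)
  } else {
    longitudinal_between <- NULL
  }

  manifest <- tibble(
    package_version = as.character(utils::packageVersion("lifescores")),
    seed = config$seed,
    n = nrow(scored),
    config_hash = rlang::hash(config)
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_stage(scored, config$out_dir, "scored_cohort")
    write_stage(summary_tbl, config$out_dir, "grouped_summary")
    for (nm in names(crosstabs)) {
      write_stage(tidy(crosstabs[[nm]]), config$out_dir,
                  paste0("crosstab_", nm))
    }
    write_stage(chisq, config$out_dir, "chi_square")
    write_stage(correlations, config$out_dir, "correlations")
    if (!is.null(cox_models)) {
      write_stage(cox_models, config$out_dir, "cox_fits")
      write_stage(age_interaction$strata, config$out_dir,
                  "age_interaction_strata")
      write_stage(age_interaction$lrt, config$out_dir, "age_interaction_lrt")
      write_stage(km$table, config$out_dir, "km_curves")
    }
    if (!is.null(longitudinal)) {
      write_stage(longitudinal, config$out_dir, "longitudinal")
      write_stage(longitudinal_between, config$out_dir,
                  "longitudinal_between_terciles")
    }
    jsonlite::write_json(as.list(manifest), file.path(config$out_dir,
                                                      "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  invisible(list(
    cohort = scored, summary = summary_tbl, crosstabs = crosstabs,
    chi_square = chisq, correlations = correlations,
    cox_models = cox_models, age_interaction = age_interaction, km = km,
    longitudinal = longitudinal,
    longitudinal_between = longitudinal_between, manifest = manifest
  ))
}
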