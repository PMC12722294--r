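# Independent oracles used across the suite. These re-derive quantities by
# brute force / direct formula evaluation and must stay independent of the
# package code paths they check.

# CONUT: literal band lookup, coded independently of conut_score()
oracle_conut <- function(albumin, cholesterol, lymphocytes) {
  alb <- if (albumin >= 35) 0 else if (albumin >= 30) 2 else if (albumin >= 25) 4 else 6
  cho <- if (cholesterol >= 4.65) 0 else if (cholesterol >= 3.62) 1 else if (cholesterol >= 2.59) 2 else 3
  lym <- if (lymphocytes >= 1.6) 0 else if (lymphocytes >= 1.2) 1 else if (lymphocytes >= 0.8) 2 else 3
  alb + cho + lym
}

# Pearson chi-square by direct Sum((O-E)^2/E)
oracle_chisq <- function(counts) {
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  sum((counts - expected)^2 / expected)
}

# Cox partial log-likelihood for a single covariate with no tied event
# times; maximized by 1-D grid+optimize search
oracle_cox_beta <- function(time, event, x) {
  stopifnot(!any(duplicated(time[event == 1])))
  pl <- function(beta) {
    sum(vapply(which(event == 1), function(i) {
      risk <- time >= time[i]
      beta * x[i] - log(sum(exp(beta * x[risk])))
    }, numeric(1)))
  }
  stats::optimize(pl, c(-10, 10), maximum = TRUE, tol = 1e-9)$maximum
}

# Product-limit estimator evaluated at the distinct event times
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (k in seq_along(ts)) {
    at_risk <- sum(time >= ts[k])
    d <- sum(time == ts[k] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  data.frame(time = ts, surv = surv)
}

# Small default config for fast tests
test_config <- function(n = 400, seed = 99, ...) {
  sim_config(n = n, seed = seed, ...)
}

# log-hazard list with selected entries overridden
hazard_with <- function(...) {
  utils::modifyList(sim_config()$log_hazard, list(...))
}

scored_test_cohort <- function(n = 800, seed = 11, ...) {
  suppressWarnings(score_cohort(generate_cohort(sim_config(n = n, seed = seed, ...))))
}
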