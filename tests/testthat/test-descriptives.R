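test_that("cross-tab row percentages recompute exactly from counts", {
  # published LS x CONUT row counts
  d <- data.frame(
    ls = rep(c("T1", "T2", "T3"), times = c(1014 + 965 + 73,
                                            1106 + 981 + 68,
                                            1109 + 728 + 68)),
    conut = c(rep(c("low", "moderate", "high"), c(1014, 965, 73)),
              rep(c("low", "moderate", "high"), c(1106, 981, 68)),
              rep(c("low", "moderate", "high"), c(1109, 728, 68)))
  )
  xt <- cross_tabulate(d, "ls", "conut")
  expect_equal(unname(xt$counts["T1", c("low", "moderate", "high")]),
               c(1014, 965, 73))
  expect_equal(round(unname(xt$row_pct["T1", c("low", "moderate", "high")]), 1),
               c(49.4, 47.0, 3.6))
  expect_equal(round(unname(xt$row_pct["T3", c("low", "moderate", "high")]), 1),
               c(58.2, 38.2, 3.6))
  expect_true(all(abs(rowSums(xt$row_pct) - 100) < 1e-9))

  # single nonzero cell -> 100% there; missing pairs dropped and counted
  d2 <- data.frame(a = c("x", "x", NA), b = c("u", "u", "u"))
  xt2 <- cross_tabulate(d2, "a", "b")
  expect_equal(unname(xt2$row_pct[1, 1]), 100)
  expect_equal(xt2$n_dropped, 1)
  expect_error(cross_tabulate(d2[0, ], "a", "b"), "complete pairs")
})

test_that("tidy() of a cross-tab pairs each count with its row percentage", {
  d <- data.frame(a = c("x", "x", "y", "y", "y"), b = c("u", "v", "u", "u", "v"))
  td <- tidy(cross_tabulate(d, "a", "b"))
  expect_equal(td$row_pct[td$a == "y" & td$b == "u"], 200 / 3, tolerance = 1e-9)
  expect_equal(sum(td$count), 5)
})

test_that("chi-square of independence matches brute-force Sum((O-E)^2/E)", {
  tab <- matrix(c(10, 20, 20, 10), 2, byrow = TRUE)
  res <- chi_square_independence(tab)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-9)
  expect_equal(res$df, 1)

  set.seed(9)
  for (i in 1:25) {
    m <- matrix(rpois(12, lambda = 40) + 5, nrow = 3)
    got <- suppressWarnings(chi_square_independence(m))
    expect_equal(got$statistic, oracle_chisq(m), tolerance = 1e-9)
    expect_equal(got$df, (nrow(m) - 1) * (ncol(m) - 1))
  }

  # perfectly proportional table: statistic 0, p = 1
  prop <- outer(c(30, 70), c(20, 40, 40)) / 10
  res0 <- chi_square_independence(prop)
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1)

  expect_error(chi_square_independence(matrix(c(0, 0, 3, 4), 2)), "marginal")
  expect_warning(chi_square_independence(matrix(c(2, 3, 4, 1), 2)), "below 5")
})

test_that("the published CONUT x cardiovascular-event table is strongly non-independent", {
  counts <- matrix(c(174, 266, 31, 4666, 3768, 316), nrow = 2, byrow = TRUE,
                   dimnames = list(c("yes", "no"), c("low", "moderate", "high")))
  res <- chi_square_independence(counts)
  expect_lt(res$p_value, 0.001)
})

test_that("ANCOVA returns p ~ 1 for identical groups and detects the simulated HDL gradient", {
  set.seed(10)
  # identical outcome and covariate blocks in every group: the group effect
  # is exactly zero, so F = 0 and p = 1
  block_y <- rnorm(20)
  block_age <- runif(20, 30, 70)
  block_sex <- sample(c("male", "female"), 20, TRUE)
  d <- data.frame(
    y = rep(block_y, 3), g = rep(c("a", "b", "c"), each = 20),
    age = rep(block_age, 3), sex = rep(block_sex, 3)
  )
  res <- adjusted_group_comparison(d, "y", "g")
  expect_equal(res$overall$p_value, 1, tolerance = 1e-6)
  expect_true(all(res$pairwise$p_value > 0.999))

  sc <- scored_test_cohort(n = 1500, seed = 12)
  res2 <- adjusted_group_comparison(sc, "hdl", "ls_tercile",
                                    covariates = c("age", "sex", "bmi"))
  expect_lt(res2$overall$p_value, 1e-6)
  adj <- res2$emmeans$emmean
  expect_true(all(diff(adj) < 0)) # monotone decreasing adjusted means
})

test_that("Tukey pairwise p-values are symmetric under group relabelling", {
  sc <- scored_test_cohort(n = 600, seed = 13)
  a <- adjusted_group_comparison(sc, "hdl", "ls_tercile")
  sc2 <- sc
  sc2$ls_tercile <- factor(sc2$ls_tercile, levels = c("T3", "T2", "T1"))
  b <- adjusted_group_comparison(sc2, "hdl", "ls_tercile")
  key <- function(x) {
    parts <- lapply(strsplit(x$contrast, " - "), sort)
    vapply(parts, paste, "", collapse = ":")
  }
  pa <- setNames(a$pairwise$p_value, key(a$pairwise))
  pb <- setNames(b$pairwise$p_value, key(b$pairwise))
  expect_equal(pa[names(pb)], pb, tolerance = 1e-9)
})

test_that("ANCOVA type-I error under the simulator's null is ~5%", {
  rej <- vapply(1:200, function(i) {
    co <- generate_cohort(sim_config(n = 240, seed = 7000 + i))
    co$g <- sample(rep(c("a", "b", "c"), each = 80)) # labels independent of outcome
    res <- adjusted_group_comparison(co, "albumin", "g")
    res$overall$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("ANCOVA rejects degenerate or collinear designs informatively", {
  d <- data.frame(y = rnorm(6), g = c("a", "a", "a", "b", "b", "b"),
                  age = 1:6, sex = rep("f", 6))
  d$age2 <- d$age * 2
  expect_error(adjusted_group_comparison(d, "y", "g",
                                         covariates = c("age", "age2")),
               "aliased|singular")
  expect_error(adjusted_group_comparison(d[c(1, 4), ], "y", "g"), ">= 2")
})

test_that("rank tests pick Kruskal-Wallis vs rank-sum by group count", {
  set.seed(14)
  d <- data.frame(y = exp(rnorm(90)), g = rep(c("a", "b", "c"), each = 30))
  expect_equal(rank_test(d, "y", "g")$method, "kruskal_wallis")
  expect_equal(rank_test(d[d$g != "c", ], "y", "g")$method,
               "wilcoxon_rank_sum")
  # identical groups: p near 1 on average; constant outcome: warning, p = 1
  d$y <- rep(1, 90)
  expect_warning(res <- rank_test(d, "y", "g"), "constant")
  expect_equal(res$p_value, 1)
  expect_error(rank_test(d[c(1, 31), ], "y", "g"), ">= 2")
  # detects a shifted lognormal group
  d2 <- data.frame(y = c(exp(rnorm(60)), exp(rnorm(60, 1))),
                   g = rep(c("a", "b"), each = 60))
  expect_lt(rank_test(d2, "y", "g")$p_value, 0.001)
})

test_that("score correlations report identity and sign-reversal correctly", {
  sc <- scored_test_cohort(n = 400, seed = 15)
  res <- score_correlations(sc)
  expect_true(all(c("spearman", "pearson", "kendall") %in% res$method))
  # identity: LS against itself via a copy column
  expect_equal(suppressWarnings(cor(sc$ls, sc$ls, method = "spearman")), 1)
  # the LS-FS correlation is positive in the simulated cohort (smoking is a
  # shared component)
  r <- res[res$x == "ls" & res$y == "framingham_risk" &
             res$method == "spearman", ]
  expect_gt(r$estimate, 0)
  expect_equal(r$n, 400)
})

test_that("correlations with < 3 complete pairs return NA with a warning", {
  sc <- scored_test_cohort(n = 10, seed = 16)
  sc$framingham_risk[-(1:2)] <- NA
  w <- capture_warnings(res <- score_correlations(sc))
  expect_true(any(grepl("fewer than 3", w)))
  expect_true(is.na(res$estimate[res$x == "ls" &
                                   res$y == "framingham_risk"][1]))
})
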