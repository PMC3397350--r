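test_that("paired t follows the textbook formula", {
  x <- c(4, 7, 2, 9)
  same <- paired_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  res <- paired_t(c(2, 3, 4), c(1, 1, 1)) # differences 1, 2, 3
  expect_equal(round(res$t, 3), 3.464)
  expect_equal(res$df, 2)

  expect_error(paired_t(c(1, 2), c(0, 1)), "zero variance")
  expect_error(paired_t(1:3, 1:4), "equal length")

  # reference implementation on random pairs
  set.seed(55)
  for (rep_i in 1:5) {
    a <- rnorm(30, mean = 1)
    b <- rnorm(30)
    ref <- stats::t.test(a, b, paired = TRUE)
    res <- paired_t(a, b)
    expect_equal(res$t, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(res$p, ref$p.value, tolerance = 1e-8)
  }
})

test_that("2 x k chi-square matches hand and reference computation", {
  flat <- chisq_2xk(rbind(c(10, 10), c(10, 10)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)

  res <- chisq_2xk(rbind(c(20, 10), c(10, 20)))
  expect_equal(round(res$statistic, 3), 6.667) # sum((O-E)^2/E), E = 15
  expect_equal(res$df, 1)

  expect_error(chisq_2xk(rbind(c(0, 5), c(0, 7))), "zero expected")
  expect_error(chisq_2xk(matrix(1, 3, 2)), "2 rows")

  set.seed(77)
  for (k in c(2, 3, 4)) {
    counts <- matrix(rpois(2 * k, 30) + 1, nrow = 2)
    ref <- stats::chisq.test(counts, correct = FALSE)
    res <- chisq_2xk(counts)
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(res$df, unname(ref$parameter))
    expect_equal(res$p, ref$p.value, tolerance = 1e-8)
  }
})

test_that("trend regression recovers slopes and flags rank deficiency", {
  q <- factor(rep(paste0("Q", 1:4), each = 10), levels = paste0("Q", 1:4))
  outcome <- 2.5 * as.integer(q) + 1
  fit <- suppressWarnings(trend_regression(outcome, q)) # perfect fit warns
  expect_equal(fit$slope, 2.5, tolerance = 1e-10)
  expect_lt(fit$p, 1e-6)

  # normal-equation oracle on a small design with covariates
  set.seed(88)
  n <- 40
  covars <- tibble::tibble(
    age_years = sample(20:70, n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    energy_kcal_day = runif(n, 1500, 3000)
  )
  qi <- sample(1:4, n, replace = TRUE)
  y <- 0.8 * qi + 0.01 * covars$age_years + rnorm(n)
  fit <- trend_regression(y, qi, covars)
  X <- cbind(
    1, qi, covars$age_years,
    as.integer(covars$sex == "female"), covars$energy_kcal_day
  )
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$slope, unname(beta[2, 1]), tolerance = 1e-10)

  # an aliased column is an error naming the term
  aliased <- dplyr::mutate(covars, energy_twice = 2 * energy_kcal_day)
  expect_error(trend_regression(y, qi, aliased), "aliased.*energy_twice")
  expect_error(trend_regression(y, rep(5L, n)), "Q1-Q4")
})

test_that("trend p-values are uniform when there is no trend", {
  set.seed(101)
  pvals <- replicate(500, {
    q <- assign_quartiles(rnorm(60))
    trend_regression(rnorm(60), q)$p
  })
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("scenario summary equals hand computation on a 5-subject cohort", {
  dri <- load_dri()
  cohort <- hand_cohort(
    n = 5,
    sex = c("male", "male", "female", "female", "female"),
    age_years = c(30L, 60L, 25L, 45L, 70L),
    zinc_total = c(9.5, 7.0, 7.5, 12.0, 40.0),
    zinc_rice = c(3.4, 1.7, 0.0, 5.1, 6.8),
    rice_g = c(200, 100, 0, 300, 400)
  )
  scens <- list(scenario("normal", 1.7), scenario("high", 3.8))
  out <- scenario_summary(cohort, scens, dri)

  ratio <- 3.8 / 1.7
  rice_new <- cohort$zinc_rice_mg_day * ratio
  total_new <- cohort$zinc_total_mg_day + cohort$zinc_rice_mg_day * (ratio - 1)
  frac <- c(0.26, 0.26, 0.34, 0.34, 0.34)
  cutoff <- c(10, 23 / 3, 23 / 3, 23 / 3, 23 / 3)
  abs_cut <- c(2.69, 2.69, 1.86, 1.86, 1.86)
  upper <- c(45, 37, 37, 37, 37)

  hi <- out[out$scenario == "high", ]
  expect_equal(hi$zinc_rice_mean, mean(rice_new), tolerance = 1e-10)
  expect_equal(hi$zinc_rice_sd, sd(rice_new), tolerance = 1e-10)
  expect_equal(
    hi$share_mean_of_shares_pct, mean(100 * rice_new / total_new),
    tolerance = 1e-10
  )
  expect_equal(
    hi$share_ratio_of_means_pct, 100 * mean(rice_new) / mean(total_new),
    tolerance = 1e-10
  )
  expect_equal(
    hi$insufficiency_pct, 100 * mean(total_new < cutoff), tolerance = 1e-10
  )
  expect_equal(
    hi$excess_pct, 100 * mean(total_new > upper), tolerance = 1e-10
  )
  expect_equal(hi$absorbed_mean, mean(frac * total_new), tolerance = 1e-10)
  expect_equal(
    hi$absorbed_inadequacy_pct, 100 * mean(frac * total_new < abs_cut),
    tolerance = 1e-10
  )
  ref_t <- paired_t(total_new, cohort$zinc_total_mg_day)
  expect_equal(hi$paired_t_vs_baseline, ref_t$t, tolerance = 1e-10)
  expect_equal(hi$paired_p_vs_baseline, ref_t$p, tolerance = 1e-10)

  # baseline row reports its own summaries and no tests
  base <- out[out$scenario == "normal", ]
  expect_equal(base$zinc_rice_mean, mean(cohort$zinc_rice_mg_day))
  expect_true(is.na(base$paired_t_vs_baseline))

  # an identical scenario compared with baseline: t = 0, p = 1
  out2 <- scenario_summary(
    cohort, list(scenario("normal", 1.7), scenario("copy", 1.7)), dri
  )
  expect_equal(out2$paired_t_vs_baseline[2], 0)
  expect_equal(out2$paired_p_vs_baseline[2], 1)
})

test_that("scenario summary is monotone across the study concentrations", {
  for (seed in c(61L, 62L)) {
    cohort <- generate_cohort(generator_config(n = 700, seed = seed))
    out <- scenario_summary(cohort)
    expect_equal(out$scenario, c("normal", "intermediate", "high"))
    expect_true(all(diff(out$zinc_rice_mean) > 0))
    expect_true(all(diff(out$absorbed_mean) > 0))
    expect_true(all(diff(out$insufficiency_pct) <= 0))
    expect_true(all(diff(out$absorbed_inadequacy_pct) <= 0))
  }
})

test_that("quartile report stratifies intake and prevalence by pattern", {
  cohort <- generate_cohort(generator_config(n = 400, seed = 71L))
  report <- quartile_report(cohort)
  patterns <- load_loadings()$patterns

  expect_s3_class(report, "quartile_report")
  expect_equal(nrow(report$cells), 4 * length(patterns))
  expect_equal(
    as.character(unique(report$cells$quartile)), paste0("Q", 1:4)
  )
  expect_true(all(report$cells$n %in% c(100, 100)))
  expect_equal(nrow(report$zinc), 4 * length(patterns) * 3)
  expect_true(all(report$zinc$insufficiency_pct >= 0 &
    report$zinc$insufficiency_pct <= 100))

  # trend rows: energy + rice + (zinc + insufficiency) per scenario
  expect_equal(nrow(report$trends), length(patterns) * (2 + 2 * 3))
  expect_true(all(report$trends$p >= 0 & report$trends$p <= 1, na.rm = TRUE))

  # per-cell means agree with a direct split
  pq <- pattern_quartiles(cohort)
  q <- pq$traditional_quartile
  direct <- tapply(cohort$rice_g_day, q, mean)
  got <- report$cells[report$cells$pattern == "traditional", ]
  expect_equal(got$rice_g_mean, as.vector(direct), tolerance = 1e-12)

  # planted structure: traditional Q4 eats more rice than Q1
  expect_gt(got$rice_g_mean[4], got$rice_g_mean[1])
})
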