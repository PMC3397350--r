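test_that("generator config rejects inconsistent settings", {
  expect_error(generator_config(n = 0), "at least 1")
  expect_error(generator_config(male_fraction = 1.2), "\\[0, 1\\]")
  expect_error(
    generator_config(age_band_probs = c(a = 0.5, b = 0.5)),
    "5 age bands"
  )
  expect_error(
    generator_config(ses_probs = c(low = 0.5, medium = 0.1, high = 0.1)),
    "sum to 1"
  )
  expect_error(generator_config(rice_sd_g = -1), "strictly positive")
  expect_error(
    generator_config(ffq_means = c(rice = 100)),
    "missing food item"
  )
  # too strong a latent effect leaves no variance for the gamma base
  expect_error(
    generate_cohort(generator_config(rice_factor_effect = 0.9, n = 10)),
    "no positive base variance"
  )
})

test_that("the same seed yields a byte-identical cohort CSV", {
  cfg <- generator_config(n = 120, seed = 99L)
  a <- withr::local_tempfile(fileext = ".csv")
  b <- withr::local_tempfile(fileext = ".csv")
  write_cohort(generate_cohort(cfg), a)
  write_cohort(generate_cohort(cfg), b)
  expect_identical(readLines(a), readLines(b))
  # and a different seed yields a different cohort
  cfg2 <- generator_config(n = 120, seed = 100L)
  expect_false(identical(
    generate_cohort(cfg2)$rice_g_day, generate_cohort(cfg)$rice_g_day
  ))
})

test_that("generated cohorts satisfy the intake invariants", {
  for (seed in c(2L, 31L)) {
    cohort <- generate_cohort(generator_config(n = 400, seed = seed))
    expect_silent(validate_cohort(cohort))
    expect_true(all(cohort$zinc_rice_mg_day <= cohort$zinc_total_mg_day))
    expect_true(all(cohort$rice_g_day >= 0))
    ffq <- as.matrix(cohort[paste0("ffq_", food_items(), "_g_wk")])
    expect_true(all(ffq >= 0))
    expect_true(all((cohort$rice_g_day == 0) == (cohort$zinc_rice_mg_day == 0)))
  }
})

test_that("default config matches the survey's rice and zinc structure", {
  cfg <- generator_config(seed = 7L)
  cohort <- generate_cohort(cfg)
  n <- nrow(cohort)
  expect_equal(n, 2819)

  # overall mean rice intake within 3 SE of 250.1 g/day
  se_rice <- 145.8 / sqrt(n * (1 - cfg$rice_nonconsumer_prob))
  expect_lt(abs(mean(cohort$rice_g_day) - 250.1), 3 * se_rice)
  # consumer SD within 10% of 145.8
  consumer_sd <- sd(cohort$rice_g_day[cohort$rice_g_day > 0])
  expect_lt(abs(consumer_sd - 145.8) / 145.8, 0.10)
  # rice non-consumers within 3 binomial SE of 5%
  se_p <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(mean(cohort$rice_g_day == 0) - 0.05), 3 * se_p)
  # total zinc close to 12.0 +/- 3.7 mg/day
  expect_lt(abs(mean(cohort$zinc_total_mg_day) - 12.0), 3 * 3.7 / sqrt(n))
  expect_lt(abs(sd(cohort$zinc_total_mg_day) - 3.7) / 3.7, 0.10)
  # male fraction within 3 binomial SE of 46.0%
  expect_lt(
    abs(mean(cohort$sex == "male") - 0.460),
    3 * sqrt(0.46 * 0.54 / n)
  )
  # age-band margins within 3 binomial SE each
  bands <- cut(cohort$age_years, c(20, 30, 40, 50, 60, Inf), right = FALSE)
  observed <- as.vector(table(bands)) / n
  for (k in seq_along(cfg$age_band_probs)) {
    p <- cfg$age_band_probs[[k]]
    expect_lt(abs(observed[k] - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("rice intake carries the planted pattern associations", {
  cohort <- generate_cohort(generator_config(seed = 5L))
  factors <- attr(cohort, "latent_factors")
  consumers <- cohort$rice_g_day > 0
  expect_gt(cor(cohort$rice_g_day[consumers], factors$traditional[consumers]), 0.1)
  expect_lt(cor(cohort$rice_g_day[consumers], factors$sweet_tooth[consumers]), -0.1)
})

test_that("degenerate noise collapses FFQ intakes to their baselines", {
  cfg <- generator_config(n = 30, noise_sd = 0, factor_loading_scale = 0, seed = 3L)
  cohort <- generate_cohort(cfg)
  for (item in food_items()) {
    expect_equal(
      cohort[[paste0("ffq_", item, "_g_wk")]],
      rep(unname(cfg$ffq_means[item]), 30)
    )
  }
})

test_that("latent factors are recovered by the scoring pipeline", {
  cohort <- generate_cohort(generator_config(seed = 13L))
  rec <- recover_factors(cohort)
  expect_identical(rec$pattern, load_loadings()$patterns)
  expect_true(all(rec$correlation > 0.7))

  # no signal: zero factor scale leaves only noise
  null_cohort <- generate_cohort(
    generator_config(n = 500, factor_loading_scale = 0, seed = 17L)
  )
  rec0 <- recover_factors(null_cohort)
  # |r| below ~3/sqrt(n): indistinguishable from zero
  expect_true(all(abs(rec0$correlation) < 3 / sqrt(500)))

  # monotonicity: doubling the factor scale does not hurt recovery
  for (seed in c(21L, 22L)) {
    r1 <- recover_factors(
      generate_cohort(generator_config(n = 800, factor_loading_scale = 120, seed = seed))
    )
    r2 <- recover_factors(
      generate_cohort(generator_config(n = 800, factor_loading_scale = 240, seed = seed))
    )
    expect_true(all(r2$correlation >= r1$correlation))
  }
})

test_that("the latent-factor sidecar round-trips and is required", {
  cohort <- generate_cohort(generator_config(n = 50, seed = 8L))
  path <- withr::local_tempfile(fileext = ".json")
  write_latent_factors(cohort, path)
  factors <- read_latent_factors(path)
  expect_equal(factors$traditional, attr(cohort, "latent_factors")$traditional)
  expect_equal(recover_factors(cohort, factors = factors),
    recover_factors(cohort),
    tolerance = 1e-12
  )

  bare <- cohort
  attr(bare, "latent_factors") <- NULL
  expect_error(recover_factors(bare), "latent factors unavailable")
  expect_error(write_latent_factors(bare, path), "no latent-factor sidecar")
})
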