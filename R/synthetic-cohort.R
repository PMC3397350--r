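#' Default mean weekly FFQ intakes (g/week)
#'
#' Plausible adult mean weekly intakes for the 25 canonical food items,
#' used as the baseline around which the latent-factor model perturbs each
#' subject's food-frequency profile. Values are round numbers on the scale
#' of a rice-staple adult diet (e.g. rice 1750 g/week is 250 g/day); they
#' set the location of each FFQ column, while the factor structure sets its
#' covariance.
#'
#' @return Named numeric vector over [food_items()].
#' @export
default_ffq_means <- function() {
  c(
    rice = 1750, wheat_flour = 700, fresh_vegetables = 2100,
    root_vegetable = 350, pickled_vegetables = 150, pork = 500,
    beef_lamb = 100, poultry = 200, liver = 50, fish = 350, eggs = 300,
    milk = 350, yoghurt = 100, milk_powder = 30, cheese = 10, tofu = 250,
    whole_grains = 200, fruits = 700, nuts = 70, cake = 100, juice = 150,
    beverage = 250, beer = 250, alcohol = 150, deep_fried_products = 100
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study conditions of the 2002 Jiangsu adult
#' survey: 2819 subjects, 46.0% male, the published age-band margins,
#' about 5% rice non-consumers, consumer rice intake averaging 263.3 g/day
#' (so the overall mean including non-consumers is about 250.1 g/day) with
#' SD 145.8 g/day, and total zinc intake of about 12.0 +/- 3.7 mg/day. The
#' non-rice zinc component (mean 7.75, SD 2.6 mg/day) is calibrated
#' analytically from those targets: the rice term at 1.7 mg/100 g
#' contributes about 4.25 +/- 2.6 mg/day, and the remainder of the total
#' mean and variance is assigned to an independent truncated normal.
#'
#' @param n Cohort size.
#' @param male_fraction Proportion of men.
#' @param age_band_probs Probabilities of the age bands 20-29, 30-39,
#'   40-49, 50-59, 60+ (must sum to 1).
#' @param region_south_prob,residence_urban_prob,ses_probs,education_probs
#'   Demographic margins (SES and education probabilities must each sum to 1).
#' @param rice_nonconsumer_prob Probability of eating no rice.
#' @param rice_mean_g,rice_sd_g Target mean and SD of daily rice intake
#'   among consumers, g/day.
#' @param rice_factor_effect Strength of the latent-factor effect on rice:
#'   a consumer's gamma-distributed base intake is multiplied by
#'   `exp(rice_factor_effect * (f_traditional - f_sweet_tooth))`, giving
#'   the traditional pattern a positive and the sweet-tooth pattern a
#'   negative association with rice. The gamma base parameters are derived
#'   so the product still meets `rice_mean_g`/`rice_sd_g`.
#' @param rice_cap_g Upper truncation for daily rice intake, g/day.
#' @param rice_zinc_mg_per_100g Zinc density of normal rice.
#' @param nonrice_zinc_mean_mg,nonrice_zinc_sd_mg Mean and SD of the
#'   non-rice zinc component, mg/day (truncated at zero).
#' @param energy_base_kcal,energy_base_sd,energy_per_rice_g Energy model:
#'   `energy = max(800, Normal(base, sd) + energy_per_rice_g * rice_g)`.
#' @param factor_loading_scale Scale `s` of the latent-factor effect on
#'   weekly FFQ grams: `w_ij = max(0, mu_j + s * sum_k L_jk f_ik + e_ij)`.
#' @param noise_sd SD of the FFQ noise term `e_ij`, g/week.
#' @param ffq_means Named vector of baseline weekly intakes `mu_j`.
#' @param seed Integer seed; one seed governs the full cohort.
#' @return A `generator_config` list.
#' @seealso [generate_cohort()]
#' @export
generator_config <- function(n = 2819,
                             male_fraction = 0.460,
                             age_band_probs = c(
                               "20-29" = 0.109, "30-39" = 0.209,
                               "40-49" = 0.216, "50-59" = 0.187,
                               "60+" = 0.279
                             ),
                             region_south_prob = 0.527,
                             residence_urban_prob = 0.249,
                             ses_probs = c(low = 0.326, medium = 0.322, high = 0.352),
                             education_probs = c(primary = 0.477, junior = 0.363, high = 0.160),
                             rice_nonconsumer_prob = 0.05,
                             rice_mean_g = 263.3,
                             rice_sd_g = 145.8,
                             rice_factor_effect = 0.15,
                             rice_cap_g = 1200,
                             rice_zinc_mg_per_100g = 1.7,
                             nonrice_zinc_mean_mg = 7.75,
                             nonrice_zinc_sd_mg = 2.6,
                             energy_base_kcal = 1500,
                             energy_base_sd = 350,
                             energy_per_rice_g = 3.46,
                             factor_loading_scale = 120,
                             noise_sd = 80,
                             ffq_means = default_ffq_means(),
                             seed = 1L) {
  config <- list(
    n = as.integer(n), male_fraction = male_fraction,
    age_band_probs = age_band_probs,
    region_south_prob = region_south_prob,
    residence_urban_prob = residence_urban_prob,
    ses_probs = ses_probs, education_probs = education_probs,
    rice_nonconsumer_prob = rice_nonconsumer_prob,
    rice_mean_g = rice_mean_g, rice_sd_g = rice_sd_g,
    rice_factor_effect = rice_factor_effect, rice_cap_g = rice_cap_g,
    rice_zinc_mg_per_100g = rice_zinc_mg_per_100g,
    nonrice_zinc_mean_mg = nonrice_zinc_mean_mg,
    nonrice_zinc_sd_mg = nonrice_zinc_sd_mg,
    energy_base_kcal = energy_base_kcal, energy_base_sd = energy_base_sd,
    energy_per_rice_g = energy_per_rice_g,
    factor_loading_scale = factor_loading_scale, noise_sd = noise_sd,
    ffq_means = ffq_means, seed = as.integer(seed)
  )
  class(config) <- "generator_config"
  validate_generator_config(config)
  config
}

validate_generator_config <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n < 1) stop("n must be at least 1", call. = FALSE)
  probs <- c(
    config$male_fraction, config$age_band_probs,
    config$region_south_prob, config$residence_urban_prob,
    config$ses_probs, config$education_probs, config$rice_nonconsumer_prob
  )
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  for (field in c("age_band_probs", "ses_probs", "education_probs")) {
    if (abs(sum(config[[field]]) - 1) > 1e-9) {
      stop(field, " must sum to 1", call. = FALSE)
    }
  }
  if (length(config$age_band_probs) != 5) {
    stop("age_band_probs must cover the 5 age bands", call. = FALSE)
  }
  positives <- c(
    rice_mean_g = config$rice_mean_g, rice_sd_g = config$rice_sd_g,
    rice_cap_g = config$rice_cap_g,
    rice_zinc_mg_per_100g = config$rice_zinc_mg_per_100g,
    nonrice_zinc_sd_mg = config$nonrice_zinc_sd_mg,
    energy_base_sd = config$energy_base_sd
  )
  if (any(positives <= 0)) {
    stop(
      "must be strictly positive: ",
      paste(names(positives)[positives <= 0], collapse = ", "),
      call. = FALSE
    )
  }
  if (config$rice_factor_effect < 0 || config$noise_sd < 0 ||
    config$factor_loading_scale < 0 || config$nonrice_zinc_mean_mg < 0) {
    stop("scales and means must be non-negative", call. = FALSE)
  }
  missing_mu <- setdiff(food_items(), names(config$ffq_means))
  if (length(missing_mu) > 0) {
    stop(
      "ffq_means is missing food item(s): ",
      paste(missing_mu, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(config)
}

# Gamma base parameters for consumer rice intake such that the product
# base * exp(tau * (f1 - f2)) has the configured mean and SD.
rice_base_params <- function(config) {
  tau <- config$rice_factor_effect
  m1 <- exp(tau^2)        # E[multiplier], Var(f1 - f2) = 2
  m2 <- exp(4 * tau^2)    # E[multiplier^2]
  base_mean <- config$rice_mean_g / m1
  base_var <- (config$rice_sd_g^2 + config$rice_mean_g^2) / m2 - base_mean^2
  if (base_var <= 0) {
    stop(
      "rice_factor_effect too large for the configured rice SD: ",
      "no positive base variance remains",
      call. = FALSE
    )
  }
  shape <- base_mean^2 / base_var
  list(shape = shape, rate = shape / base_mean)
}

sample_age <- function(band, n_band) {
  lo <- c("20-29" = 20, "30-39" = 30, "40-49" = 40, "50-59" = 50, "60+" = 60)
  hi <- c("20-29" = 29, "30-39" = 39, "40-49" = 49, "50-59" = 59, "60+" = 80)
  sample(seq(lo[[band]], hi[[band]]), n_band, replace = TRUE)
}

#' Generate a synthetic survey cohort
#'
#' Draws a cohort deterministically from `config$seed`. Demographics are
#' sampled independently from their margins. Rice intake is zero with the
#' non-consumer probability and otherwise gamma-distributed (right-skewed,
#' as intake data are) times a latent-factor multiplier that ties rice
#' positively to the traditional factor and negatively to the sweet-tooth
#' factor, truncated at `rice_cap_g`. Zinc from rice is
#' `rice_g x density / 100`; total zinc adds an independent truncated-normal
#' non-rice component. Weekly FFQ grams follow a 4-latent-factor model with
#' independent standard-normal factors and the packaged loading matrix,
#' rectified at zero.
#'
#' The latent factors are attached as attribute `"latent_factors"` (a
#' tibble: `id` plus one column per pattern) so generator validation via
#' [recover_factors()] can compare them with computed pattern scores; the
#' attribute can be persisted with [write_latent_factors()].
#'
#' @param config A [generator_config()].
#' @param loadings A `factor_loadings` object; defaults to the packaged
#'   matrix.
#' @return A validated cohort tibble of `config$n` rows with attribute
#'   `"latent_factors"`.
#' @examples
#' cohort <- generate_cohort(generator_config(n = 200, seed = 42))
#' mean(cohort$rice_g_day)
#' @export
generate_cohort <- function(config = generator_config(),
                            loadings = load_loadings()) {
  validate_generator_config(config)
  stopifnot(inherits(loadings, "factor_loadings"))
  n <- config$n
  set.seed(config$seed)

  sex <- ifelse(stats::runif(n) < config$male_fraction, "male", "female")
  bands <- sample(names(config$age_band_probs), n,
    replace = TRUE, prob = config$age_band_probs
  )
  age <- integer(n)
  for (band in names(config$age_band_probs)) {
    idx <- which(bands == band)
    if (length(idx) > 0) age[idx] <- sample_age(band, length(idx))
  }
  region <- ifelse(stats::runif(n) < config$region_south_prob, "south", "north")
  residence <- ifelse(stats::runif(n) < config$residence_urban_prob, "urban", "rural")
  ses <- sample(names(config$ses_probs), n, replace = TRUE, prob = config$ses_probs)
  education <- sample(names(config$education_probs), n,
    replace = TRUE, prob = config$education_probs
  )

  patterns <- loadings$patterns
  factors <- matrix(stats::rnorm(n * length(patterns)),
    nrow = n, dimnames = list(NULL, patterns)
  )

  consumer <- stats::runif(n) >= config$rice_nonconsumer_prob
  base <- rice_base_params(config)
  rice_base <- stats::rgamma(n, shape = base$shape, rate = base$rate)
  multiplier <- exp(
    config$rice_factor_effect *
      (factors[, "traditional"] - factors[, "sweet_tooth"])
  )
  rice <- pmin(rice_base * multiplier, config$rice_cap_g)
  rice[!consumer] <- 0

  zinc_rice <- rice * config$rice_zinc_mg_per_100g / 100
  nonrice <- pmax(
    0,
    stats::rnorm(n, config$nonrice_zinc_mean_mg, config$nonrice_zinc_sd_mg)
  )
  zinc_total <- zinc_rice + nonrice
  energy <- pmax(
    800,
    stats::rnorm(n, config$energy_base_kcal, config$energy_base_sd) +
      config$energy_per_rice_g * rice
  )

  items <- food_items()
  loading_mat <- matrix(0,
    nrow = length(items), ncol = length(patterns),
    dimnames = list(items, patterns)
  )
  for (r in seq_len(nrow(loadings$loadings))) {
    row <- loadings$loadings[r, ]
    loading_mat[row$food_item, row$pattern] <- row$loading
  }
  mu <- config$ffq_means[items]
  noise <- matrix(stats::rnorm(n * length(items), sd = config$noise_sd), nrow = n)
  ffq <- sweep(
    config$factor_loading_scale * factors %*% t(loading_mat) + noise,
    2, mu, `+`
  )
  ffq <- pmax(ffq, 0)
  colnames(ffq) <- ffq_col(items)

  id <- sprintf("S%04d", seq_len(n))
  cohort <- tibble::tibble(
    id = id, sex = sex, age_years = as.integer(age), region = region,
    residence = residence, ses = ses, education = education,
    energy_kcal_day = energy, zinc_total_mg_day = zinc_total,
    zinc_rice_mg_day = zinc_rice, rice_g_day = rice
  )
  cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(ffq))
  validate_cohort(cohort)
  attr(cohort, "latent_factors") <- dplyr::bind_cols(
    tibble::tibble(id = id), tibble::as_tibble(factors)
  )
  cohort
}

#' Persist or reload the latent-factor sidecar
#'
#' The latent factors behind a synthetic cohort are simulation metadata,
#' not survey fields, so they travel in a JSON sidecar rather than in the
#' cohort CSV.
#'
#' @param cohort A cohort from [generate_cohort()] (or any tibble with a
#'   `latent_factors` attribute).
#' @param path Sidecar JSON path.
#' @return `write_latent_factors()` returns `path` invisibly;
#'   `read_latent_factors()` returns the factor tibble.
#' @export
write_latent_factors <- function(cohort, path) {
  factors <- attr(cohort, "latent_factors")
  if (is.null(factors)) {
    stop("cohort carries no latent-factor sidecar", call. = FALSE)
  }
  jsonlite::write_json(factors, path, digits = NA)
  invisible(path)
}

#' @rdname write_latent_factors
#' @export
read_latent_factors <- function(path) {
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Parameter recovery: latent factors vs computed pattern scores
#'
#' Validates the generator end to end: standardizes the cohort's FFQ,
#' computes pattern scores with the same loading matrix the generator
#' used, and correlates each score with the latent factor that generated
#' it. High correlations mean the scoring pipeline recovers the planted
#' factor structure.
#'
#' @param cohort A cohort tibble.
#' @param loadings A `factor_loadings` object.
#' @param factors The latent-factor tibble; defaults to the cohort's
#'   sidecar attribute. An error is raised if neither is available.
#' @return Tibble with columns `pattern` and `correlation`.
#' @export
recover_factors <- function(cohort, loadings = load_loadings(),
                            factors = attr(cohort, "latent_factors")) {
  if (is.null(factors)) {
    stop(
      "latent factors unavailable: pass `factors` or use a cohort with ",
      "its sidecar attribute",
      call. = FALSE
    )
  }
  if (!identical(factors$id, cohort$id)) {
    stop("latent-factor sidecar does not match the cohort ids", call. = FALSE)
  }
  z <- standardize_ffq(cohort)
  scores <- score_patterns(z, loadings)
  tibble::tibble(
    pattern = loadings$patterns,
    correlation = purrr::map_dbl(
      loadings$patterns,
      ~ stats::cor(scores[[.x]], factors[[.x]])
    )
  )
}
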