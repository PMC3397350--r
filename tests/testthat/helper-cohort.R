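# Build a small fully-specified cohort by hand. Intakes default to simple
# consistent values; FFQ columns default to zero and can be overridden with
# ffq = list(food_item = c(...)) vectors.
hand_cohort <- function(n = 3,
                        sex = rep("male", n),
                        age_years = rep(30L, n),
                        energy = rep(2000, n),
                        zinc_total = rep(12, n),
                        zinc_rice = rep(4, n),
                        rice_g = rep(4 / 1.7 * 100, n),
                        ffq = list()) {
  cohort <- tibble::tibble(
    id = sprintf("H%02d", seq_len(n)),
    sex = sex,
    age_years = as.integer(age_years),
    region = rep("south", n),
    residence = rep("rural", n),
    ses = rep("medium", n),
    education = rep("primary", n),
    energy_kcal_day = energy,
    zinc_total_mg_day = zinc_total,
    zinc_rice_mg_day = zinc_rice,
    rice_g_day = rice_g
  )
  for (item in zincsim::food_items()) {
    col <- paste0("ffq_", item, "_g_wk")
    cohort[[col]] <- if (!is.null(ffq[[item]])) ffq[[item]] else rep(0, n)
  }
  cohort
}

# Random valid cohort for round-trip and oracle tests (not the package
# generator: independent construction).
random_cohort <- function(n, seed) {
  set.seed(seed)
  rice <- ifelse(runif(n) < 0.1, 0, rgamma(n, 4, rate = 1 / 60))
  ffq <- stats::setNames(
    lapply(zincsim::food_items(), function(i) round(rexp(n, 1 / 300), 3)),
    zincsim::food_items()
  )
  hand_cohort(
    n = n,
    sex = sample(c("male", "female"), n, replace = TRUE),
    age_years = sample(20:80, n, replace = TRUE),
    energy = runif(n, 1200, 3500),
    zinc_total = rice * 0.017 + runif(n, 2, 15),
    zinc_rice = rice * 0.017,
    rice_g = rice,
    ffq = ffq
  )
}
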