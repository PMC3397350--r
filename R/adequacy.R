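#' Insufficiency cutoff for zinc intake
#'
#' Two-thirds of the age/sex-specific RNI: 10.0 mg/day for men aged 20-49
#' (2/3 of 15) and 23/3 ~ 7.667 mg/day for older men and for all women
#' (2/3 of 11.5).
#'
#' @param sex,age_years Vectorised subject strata; ages below 20 error.
#' @param dri A `dri_table`.
#' @return Cutoff in mg/day.
#' @examples
#' dri <- load_dri()
#' insufficiency_cutoff("male", 30, dri)
#' @export
insufficiency_cutoff <- function(sex, age_years, dri = load_dri()) {
  dri$insufficiency_fraction * rni(dri, sex, age_years)
}

#' Absorbed zinc
#'
#' Intake times the sex-specific fractional absorption for a mixed diet
#' (IZiNCG: 26% for men, 34% for women).
#'
#' @param intake_mg_day Daily zinc intake.
#' @param sex Vectorised sex.
#' @param dri A `dri_table`.
#' @return Absorbed zinc, mg/day.
#' @export
absorbed_zinc <- function(intake_mg_day, sex, dri = load_dri()) {
  if (any(intake_mg_day < 0)) stop("intake must be non-negative", call. = FALSE)
  absorption_fraction(dri, sex) * intake_mg_day
}

#' Classify zinc intake adequacy
#'
#' For each subject: insufficient if intake is strictly below 2/3 of the
#' age/sex RNI; excess if strictly above the tolerable upper intake level
#' (45 mg/day for men aged 20-50, 37 otherwise); absorbed zinc as
#' fractional absorption times intake; absorbed-inadequate if absorbed
#' zinc is strictly below 2.69 mg/day (men) or 1.86 mg/day (women). The
#' strict inequalities follow the definitions ("below", "higher than").
#' Intake insufficiency and absorbed inadequacy are two separate rule
#' systems and need not coincide: a man aged 20-49 at exactly the 10.0
#' mg/day cutoff absorbs 2.60 mg/day, below the 2.69 absorbed cutoff.
#'
#' @param intake_mg_day Daily zinc intake (vectorised).
#' @param sex,age_years Subject strata.
#' @param dri A `dri_table`.
#' @param subject_id Optional ids for the output.
#' @return Tibble: `subject_id`, `cutoff_mg_day`, `insufficient`,
#'   `excess`, `absorbed_mg_day`, `absorbed_inadequate`.
#' @examples
#' classify_adequacy(c(9.9, 46), c("male", "male"), c(30, 40))
#' @export
classify_adequacy <- function(intake_mg_day, sex, age_years,
                              dri = load_dri(),
                              subject_id = as.character(seq_along(intake_mg_day))) {
  if (any(intake_mg_day < 0)) stop("intake must be non-negative", call. = FALSE)
  cutoff <- insufficiency_cutoff(sex, age_years, dri)
  upper <- ul(dri, sex, age_years)
  absorbed <- absorbed_zinc(intake_mg_day, sex, dri)
  tibble::tibble(
    subject_id = subject_id,
    cutoff_mg_day = cutoff,
    insufficient = intake_mg_day < cutoff,
    excess = intake_mg_day > upper,
    absorbed_mg_day = absorbed,
    absorbed_inadequate = absorbed < absorbed_inadequacy_cutoff(dri, sex)
  )
}

clopper_pearson <- function(x, n) {
  ci <- stats::binom.test(x, n)$conf.int
  c(lower = ci[1], upper = ci[2])
}

#' Prevalence summary with exact binomial intervals
#'
#' Percentages of insufficient, excess and absorbed-inadequate subjects,
#' each with its Clopper-Pearson exact 95% confidence interval.
#'
#' @param results Classification tibble from [classify_adequacy()].
#' @return Tibble with one row per measure: `measure`, `count`, `n`,
#'   `pct`, `lower_pct`, `upper_pct`.
#' @export
prevalence <- function(results) {
  if (nrow(results) == 0) {
    stop("prevalence undefined for an empty cohort", call. = FALSE)
  }
  n <- nrow(results)
  measures <- c(
    insufficiency = "insufficient",
    excess = "excess",
    absorbed_inadequacy = "absorbed_inadequate"
  )
  purrr::imap(measures, function(col, measure) {
    x <- sum(results[[col]])
    ci <- clopper_pearson(x, n)
    tibble::tibble(
      measure = measure, count = x, n = n, pct = 100 * x / n,
      lower_pct = 100 * ci[["lower"]], upper_pct = 100 * ci[["upper"]]
    )
  }) |>
    dplyr::bind_rows()
}
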