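#' @keywords internal
cohort_demographic_cols <- function() {
  c("id", "sex", "age_years", "region", "residence", "ses", "education")
}

cohort_intake_cols <- function() {
  c("energy_kcal_day", "zinc_total_mg_day", "zinc_rice_mg_day", "rice_g_day")
}

cohort_levels <- list(
  sex = c("male", "female"),
  region = c("north", "south"),
  residence = c("urban", "rural"),
  ses = c("low", "medium", "high"),
  education = c("primary", "junior", "high")
)

#' Validate a cohort table
#'
#' Checks the cohort schema (demographics, the four derived daily intakes
#' and one weekly FFQ column per canonical food item) and the per-subject
#' invariants: all intakes non-negative, zinc from rice never exceeding
#' total zinc, rice grams zero exactly when zinc from rice is zero, and all
#' ages at least 20 (the study population is adults).
#'
#' @param cohort A cohort tibble.
#' @return The cohort, invisibly, if valid; otherwise an error naming the
#'   offending column or row.
#' @export
validate_cohort <- function(cohort) {
  required <- c(
    cohort_demographic_cols(), cohort_intake_cols(),
    ffq_col(food_items())
  )
  missing <- setdiff(required, names(cohort))
  if (length(missing) > 0) {
    stop(
      "cohort is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(cohort$id)) {
    stop("cohort has duplicated subject ids", call. = FALSE)
  }
  for (col in names(cohort_levels)) {
    bad <- !cohort[[col]] %in% cohort_levels[[col]]
    if (any(bad)) {
      stop(
        "invalid ", col, " value(s) in row(s) ",
        paste(utils::head(which(bad), 5), collapse = ", "),
        call. = FALSE
      )
    }
  }
  if (any(cohort$age_years < 20)) {
    stop(
      "age below 20 in row(s) ",
      paste(utils::head(which(cohort$age_years < 20), 5), collapse = ", "),
      call. = FALSE
    )
  }
  numeric_cols <- c(cohort_intake_cols(), ffq_col(food_items()))
  for (col in numeric_cols) {
    bad <- !is.finite(cohort[[col]]) | cohort[[col]] < 0
    if (any(bad)) {
      stop(
        "negative or non-finite ", col, " for subject id ",
        cohort$id[which(bad)[1]], " (row ", which(bad)[1], ")",
        call. = FALSE
      )
    }
  }
  bad <- cohort$zinc_rice_mg_day > cohort$zinc_total_mg_day
  if (any(bad)) {
    stop(
      "zinc from rice exceeds total zinc for subject id ",
      cohort$id[which(bad)[1]], " (row ", which(bad)[1], ")",
      call. = FALSE
    )
  }
  bad <- (cohort$rice_g_day == 0) != (cohort$zinc_rice_mg_day == 0)
  if (any(bad)) {
    stop(
      "rice grams and zinc from rice must be zero together; violated for ",
      "subject id ", cohort$id[which(bad)[1]], " (row ", which(bad)[1], ")",
      call. = FALSE
    )
  }
  invisible(cohort)
}

#' Read a cohort CSV
#'
#' One row per subject; comma-separated, UTF-8, header required. Units are
#' carried in the column names (`*_mg_day`, `*_g_day`, `ffq_*_g_wk`). Row
#' order is preserved.
#'
#' @param path CSV file path.
#' @return A validated cohort tibble.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path) {
  # base read.csv: its strtod parse is exact to the last ulp, which the
  # round-trip contract requires
  cohort <- tibble::as_tibble(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  )
  for (col in setdiff(cohort_demographic_cols(), "age_years")) {
    if (col %in% names(cohort)) cohort[[col]] <- as.character(cohort[[col]])
  }
  if ("age_years" %in% names(cohort)) {
    cohort$age_years <- as.integer(cohort$age_years)
  }
  numeric_cols <- intersect(
    c(cohort_intake_cols(), ffq_col(food_items())), names(cohort)
  )
  for (col in numeric_cols) cohort[[col]] <- as.numeric(cohort[[col]])
  validate_cohort(cohort)
  cohort
}

#' Write a cohort CSV
#'
#' Numeric fields are written in their shortest round-trippable decimal
#' representation, so `write_cohort()` followed by [read_cohort()]
#' reproduces the cohort exactly, to full double precision.
#'
#' @param cohort A valid cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  out <- cohort
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      # 17 significant digits round-trip any double exactly
      out[[col]] <- sub("^(\\d+)\\.?0*$", "\\1", sprintf("%.17g", out[[col]]))
    }
  }
  readr::write_csv(out, path)
  invisible(path)
}
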