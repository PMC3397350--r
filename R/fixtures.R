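#' Load a factor-loading matrix
#'
#' Reads a JSON fixture holding the loadings of the four dietary patterns
#' (`traditional`, `macho`, `sweet_tooth`, `healthy`) on the FFQ food
#' items. Pattern scores use only items whose absolute loading is at least
#' the inclusion threshold (0.20 in the published table), so the fixture
#' must not carry any entry below it.
#'
#' @param path Path to the JSON fixture; defaults to the packaged table.
#' @return An object of class `factor_loadings`: a list with `patterns`
#'   (ordered character vector), `inclusion_threshold`, and `loadings`, a
#'   tibble with columns `food_item`, `pattern`, `loading`.
#' @examples
#' fl <- load_loadings()
#' subset(fl$loadings, food_item == "rice")
#' @export
load_loadings <- function(path = zincsim_fixture("loadings")) {
  raw <- jsonlite::read_json(path)
  for (field in c("patterns", "inclusion_threshold", "loadings")) {
    if (is.null(raw[[field]])) {
      stop("loading fixture is missing field '", field, "'", call. = FALSE)
    }
  }
  patterns <- as.character(unlist(raw$patterns))
  threshold <- as.numeric(raw$inclusion_threshold)
  loadings <- purrr::imap(raw$loadings, function(items, pat) {
    tibble::tibble(
      food_item = names(items),
      pattern = pat,
      loading = as.numeric(unlist(items))
    )
  })
  loadings <- dplyr::bind_rows(loadings)

  if (!setequal(names(raw$loadings), patterns)) {
    stop("loading fixture patterns do not match its pattern list", call. = FALSE)
  }
  bad_range <- abs(loadings$loading) > 1
  if (any(bad_range)) {
    stop(
      "loadings outside [-1, 1]: ",
      paste(loadings$food_item[bad_range], collapse = ", "),
      call. = FALSE
    )
  }
  below <- abs(loadings$loading) < threshold
  if (any(below)) {
    stop(
      "loadings below the inclusion threshold ", threshold, ": ",
      paste(loadings$food_item[below], collapse = ", "),
      call. = FALSE
    )
  }
  unknown <- setdiff(loadings$food_item, food_items())
  if (length(unknown) > 0) {
    stop(
      "loading fixture names food items outside the canonical vocabulary: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }

  structure(
    list(
      patterns = patterns,
      inclusion_threshold = threshold,
      loadings = loadings
    ),
    class = "factor_loadings"
  )
}

#' Look up one loading
#'
#' @param loadings A `factor_loadings` object.
#' @param food_item,pattern Names to look up.
#' @return The loading, or 0 if the item was not retained on that pattern.
#' @export
loading_of <- function(loadings, food_item, pattern) {
  stopifnot(inherits(loadings, "factor_loadings"))
  hit <- loadings$loadings$food_item == food_item &
    loadings$loadings$pattern == pattern
  if (!any(hit)) return(0)
  loadings$loadings$loading[hit]
}

parse_age_rules <- function(rules, what, sex) {
  if (is.null(rules)) {
    stop("DRI fixture is missing ", what, " rules for sex '", sex, "'",
      call. = FALSE
    )
  }
  purrr::map(rules, function(r) {
    list(
      age_min = as.numeric(r$age_min),
      age_max = if (is.null(r$age_max)) Inf else as.numeric(r$age_max),
      value = as.numeric(r$value)
    )
  })
}

#' Load the zinc dietary-reference table
#'
#' Reads a JSON fixture holding age/sex-specific RNI and tolerable upper
#' intake levels (UL), the insufficiency fraction (2/3 of RNI), sex-specific
#' fractional absorption for a mixed diet and absorbed-zinc inadequacy
#' cutoffs. Note the reference values split the male RNI strata at 49/50
#' years but the male UL strata at 50/51 years; this mismatch is part of
#' the reference table and is preserved.
#'
#' @param path Path to the JSON fixture; defaults to the packaged table.
#' @return An object of class `dri_table`.
#' @examples
#' dri <- load_dri()
#' rni(dri, "male", 30)
#' @export
load_dri <- function(path = zincsim_fixture("dri")) {
  raw <- jsonlite::read_json(path)
  for (field in c(
    "rni_mg_day", "insufficiency_fraction", "ul_mg_day",
    "absorption_fraction", "absorbed_inadequacy_mg_day"
  )) {
    if (is.null(raw[[field]])) {
      stop("DRI fixture is missing field '", field, "'", call. = FALSE)
    }
  }
  for (sex in c("male", "female")) {
    for (field in c("absorption_fraction", "absorbed_inadequacy_mg_day")) {
      if (is.null(raw[[field]][[sex]])) {
        stop("DRI fixture is missing ", field, " for sex '", sex, "'",
          call. = FALSE
        )
      }
    }
  }
  frac <- raw$insufficiency_fraction
  frac <- if (is.list(frac)) {
    as.numeric(frac$numerator) / as.numeric(frac$denominator)
  } else {
    as.numeric(frac)
  }
  dri <- structure(
    list(
      rni = list(
        male = parse_age_rules(raw$rni_mg_day$male, "RNI", "male"),
        female = parse_age_rules(raw$rni_mg_day$female, "RNI", "female")
      ),
      insufficiency_fraction = frac,
      ul = list(
        male = parse_age_rules(raw$ul_mg_day$male, "UL", "male"),
        female = parse_age_rules(raw$ul_mg_day$female, "UL", "female")
      ),
      absorption_fraction = list(
        male = as.numeric(raw$absorption_fraction$male),
        female = as.numeric(raw$absorption_fraction$female)
      ),
      absorbed_inadequacy = list(
        male = as.numeric(raw$absorbed_inadequacy_mg_day$male),
        female = as.numeric(raw$absorbed_inadequacy_mg_day$female)
      )
    ),
    class = "dri_table"
  )
  all_values <- c(
    unlist(purrr::map(c(dri$rni, dri$ul), ~ purrr::map_dbl(.x, "value"))),
    dri$insufficiency_fraction,
    unlist(dri$absorption_fraction),
    unlist(dri$absorbed_inadequacy)
  )
  if (any(!is.finite(all_values)) || any(all_values <= 0)) {
    stop("DRI fixture values must all be strictly positive", call. = FALSE)
  }
  dri
}

lookup_age_rule <- function(rules, age_years, what, sex) {
  for (r in rules) {
    if (age_years >= r$age_min && age_years <= r$age_max) return(r$value)
  }
  stop("no ", what, " stratum covers ", sex, " aged ", age_years, call. = FALSE)
}

check_adult_age <- function(age_years) {
  if (any(age_years < 20)) {
    stop("age below 20 is outside the study population", call. = FALSE)
  }
}

#' Reference-value accessors
#'
#' Vectorised over `sex` and `age_years`. `rni()` is the recommended
#' nutrient intake, `ul()` the tolerable upper intake level (both mg/day),
#' `absorption_fraction()` the fraction of dietary zinc absorbed on a mixed
#' diet, and `absorbed_inadequacy_cutoff()` the absorbed-zinc level (mg/day)
#' below which absorbed intake is classified inadequate.
#'
#' @param dri A `dri_table`.
#' @param sex `"male"` or `"female"`.
#' @param age_years Age in completed years, at least 20.
#' @return Numeric vector.
#' @name dri-accessors
NULL

#' @rdname dri-accessors
#' @export
rni <- function(dri, sex, age_years) {
  stopifnot(inherits(dri, "dri_table"))
  check_adult_age(age_years)
  mapply(
    function(s, a) lookup_age_rule(dri$rni[[s]], a, "RNI", s),
    sex, age_years, USE.NAMES = FALSE
  )
}

#' @rdname dri-accessors
#' @export
ul <- function(dri, sex, age_years) {
  stopifnot(inherits(dri, "dri_table"))
  check_adult_age(age_years)
  mapply(
    function(s, a) lookup_age_rule(dri$ul[[s]], a, "UL", s),
    sex, age_years, USE.NAMES = FALSE
  )
}

#' @rdname dri-accessors
#' @export
absorption_fraction <- function(dri, sex) {
  stopifnot(inherits(dri, "dri_table"))
  purrr::map_dbl(sex, ~ dri$absorption_fraction[[.x]])
}

#' @rdname dri-accessors
#' @export
absorbed_inadequacy_cutoff <- function(dri, sex) {
  stopifnot(inherits(dri, "dri_table"))
  purrr::map_dbl(sex, ~ dri$absorbed_inadequacy[[.x]])
}

#' Load a food-composition table
#'
#' @param path CSV with columns `food_item`, `zinc_mg_per_100g`,
#'   `energy_kcal_per_100g`; defaults to the packaged demonstration table
#'   (rice carries the 2002 China Food Composition Table zinc density of
#'   1.7 mg/100 g; the other rows are synthetic plausible values).
#' @return Tibble with one row per food item.
#' @export
load_composition <- function(path = zincsim_fixture("composition")) {
  comp <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("food_item", "zinc_mg_per_100g", "energy_kcal_per_100g")
  missing <- setdiff(required, names(comp))
  if (length(missing) > 0) {
    stop(
      "composition table is missing column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(comp$zinc_mg_per_100g < 0) || any(comp$energy_kcal_per_100g < 0)) {
    stop("composition densities must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(comp$food_item)) {
    stop("composition table has duplicated food items", call. = FALSE)
  }
  comp[required]
}
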