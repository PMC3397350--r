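#' Compute daily zinc and energy intakes from recall lines
#'
#' Sums `grams/100 x density` over a subject's recall-style food
#' quantities (3-day-mean g/day per food) against a composition table, and
#' isolates the zinc contributed by rice. Unknown food items are an error,
#' never silently dropped.
#'
#' @param lines Tibble of recall lines: `subject_id`, `food_item`,
#'   `grams_per_day` (non-negative).
#' @param composition Composition tibble as from [load_composition()].
#' @param rice_item Food-item name identifying rice.
#' @return Tibble with one row per subject: `subject_id`,
#'   `zinc_total_mg_day`, `zinc_rice_mg_day`, `energy_kcal_day`. Subjects
#'   with no lines get all-zero intakes only if they appear in `lines`
#'   with zero grams; an empty `lines` yields an empty result.
#' @examples
#' comp <- load_composition()
#' lines <- tibble::tibble(
#'   subject_id = "a", food_item = "rice", grams_per_day = 250
#' )
#' compute_intakes(lines, comp)
#' @export
compute_intakes <- function(lines, composition, rice_item = "rice") {
  required <- c("subject_id", "food_item", "grams_per_day")
  missing <- setdiff(required, names(lines))
  if (length(missing) > 0) {
    stop(
      "recall lines missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(lines$grams_per_day < 0)) {
    stop("recall grams must be non-negative", call. = FALSE)
  }
  unknown <- setdiff(unique(lines$food_item), composition$food_item)
  if (length(unknown) > 0) {
    stop(
      "food item(s) absent from the composition table: ",
      paste(sort(unknown), collapse = ", "),
      call. = FALSE
    )
  }
  lines |>
    dplyr::inner_join(composition, by = "food_item") |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      zinc_total_mg_day = sum(.data$grams_per_day / 100 * .data$zinc_mg_per_100g),
      zinc_rice_mg_day = sum(
        (.data$grams_per_day / 100 * .data$zinc_mg_per_100g)[
          .data$food_item == rice_item
        ]
      ),
      energy_kcal_day = sum(.data$grams_per_day / 100 * .data$energy_kcal_per_100g),
      .groups = "drop"
    )
}

# Molar masses, g/mol: phytic acid C6H18O24P6 and elemental zinc.
PHYTATE_MOLAR_MASS <- 660.04
ZINC_MOLAR_MASS <- 65.38

#' Phytate:zinc molar ratio
#'
#' Moles of phytic acid per mole of zinc in a food, the standard index of
#' how strongly a food's phytate inhibits zinc absorption (ratios above ~15
#' indicate poor bioavailability). Uses molar masses of 660.04 g/mol
#' (phytic acid) and 65.38 g/mol (zinc).
#'
#' @param phytate_mg_per_100g Phytate density, mg/100 g (non-negative).
#' @param zinc_mg_per_100g Zinc density, mg/100 g (strictly positive).
#' @return The molar ratio.
#' @examples
#' phytate_zinc_molar_ratio(290, 3.8) # biofortified variety, ~7.6
#' @export
phytate_zinc_molar_ratio <- function(phytate_mg_per_100g, zinc_mg_per_100g) {
  if (any(phytate_mg_per_100g < 0)) {
    stop("phytate density must be non-negative", call. = FALSE)
  }
  if (any(zinc_mg_per_100g <= 0)) {
    stop("molar ratio undefined for zero zinc density", call. = FALSE)
  }
  (phytate_mg_per_100g / PHYTATE_MOLAR_MASS) /
    (zinc_mg_per_100g / ZINC_MOLAR_MASS)
}
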