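#' Standardize weekly FFQ intakes
#'
#' Converts each FFQ column to cohort-wide z-scores,
#' `z = (w - mean) / sd`, with the sample SD (denominator n-1). A food
#' with zero variance cannot be standardized; its z-scores are set to 0
#' for every subject with a warning, which removes it from pattern scores.
#'
#' @param cohort A cohort tibble with the canonical FFQ columns.
#' @return Tibble: `id` plus one z-score column per food item (bare item
#'   names, no `ffq_` prefix).
#' @export
standardize_ffq <- function(cohort) {
  if (nrow(cohort) < 2) {
    stop("standardization needs at least 2 subjects", call. = FALSE)
  }
  cols <- ffq_col(food_items())
  missing <- setdiff(cols, names(cohort))
  if (length(missing) > 0) {
    stop(
      "cohort is missing FFQ column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  z <- purrr::map(cols, function(col) {
    w <- cohort[[col]]
    s <- stats::sd(w)
    if (s == 0) {
      warning(
        "zero variance in ", col, "; z-scores set to 0",
        call. = FALSE
      )
      rep(0, length(w))
    } else {
      (w - mean(w)) / s
    }
  })
  names(z) <- food_items()
  dplyr::bind_cols(tibble::tibble(id = cohort$id), tibble::as_tibble(z))
}

#' Compute dietary-pattern scores
#'
#' A subject's score on a pattern is the sum over the pattern's retained
#' food items (those with absolute loading at or above the inclusion
#' threshold) of loading times standardized weekly intake.
#'
#' @param z Standardized intakes from [standardize_ffq()].
#' @param loadings A `factor_loadings` object.
#' @return Tibble: `id` plus one score column per pattern.
#' @examples
#' cohort <- generate_cohort(generator_config(n = 50, seed = 7))
#' scores <- score_patterns(standardize_ffq(cohort), load_loadings())
#' head(scores)
#' @export
score_patterns <- function(z, loadings) {
  stopifnot(inherits(loadings, "factor_loadings"))
  needed <- unique(loadings$loadings$food_item)
  missing <- setdiff(needed, names(z))
  if (length(missing) > 0) {
    stop(
      "standardized intakes missing food item(s) with retained loadings: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  scores <- purrr::map(loadings$patterns, function(pat) {
    rows <- loadings$loadings[loadings$loadings$pattern == pat, ]
    zmat <- as.matrix(z[rows$food_item])
    as.numeric(zmat %*% rows$loading)
  })
  names(scores) <- loadings$patterns
  dplyr::bind_cols(tibble::tibble(id = z$id), tibble::as_tibble(scores))
}

#' Assign population quartiles
#'
#' Rank-based quartiles: subjects are sorted ascending by score (ties kept
#' in original input order, so the split is stable and reproducible) and
#' cut at ranks `ceiling(n/4)`, `ceiling(n/2)` and `ceiling(3n/4)`. Group
#' sizes therefore differ by at most 1; Q1 is the lowest quarter and Q4
#' the highest.
#'
#' @param scores Numeric vector, length at least 4.
#' @return Factor with levels `Q1` to `Q4`, aligned with `scores`.
#' @examples
#' assign_quartiles(c(5, 1, 3, 7, 2, 8, 6, 4))
#' @export
assign_quartiles <- function(scores) {
  n <- length(scores)
  if (n < 4) stop("quartiles need at least 4 subjects", call. = FALSE)
  if (any(!is.finite(scores))) {
    stop("scores must be finite", call. = FALSE)
  }
  ord <- order(scores) # radix sort: stable for ties
  rank_of <- integer(n)
  rank_of[ord] <- seq_len(n)
  cuts <- ceiling(c(n / 4, n / 2, 3 * n / 4))
  q <- 1L + (rank_of > cuts[1]) + (rank_of > cuts[2]) + (rank_of > cuts[3])
  factor(paste0("Q", q), levels = paste0("Q", 1:4))
}

#' Score a cohort and assign quartiles in one step
#'
#' @param cohort A cohort tibble.
#' @param loadings A `factor_loadings` object.
#' @return Tibble: `id`, one score column per pattern, and one
#'   `<pattern>_quartile` factor column per pattern.
#' @export
pattern_quartiles <- function(cohort, loadings = load_loadings()) {
  scores <- score_patterns(standardize_ffq(cohort), loadings)
  for (pat in loadings$patterns) {
    scores[[paste0(pat, "_quartile")]] <- assign_quartiles(scores[[pat]])
  }
  scores
}
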