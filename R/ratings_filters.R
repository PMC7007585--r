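# Inclusion filters and confidence labelling for long-format ratings.
#
# Pipeline order (fixed): drop_invalid -> cap_rounds ->
# drop_incomplete_rounds -> select_rateable_images; then label_confidence.

#' Filter policy
#'
#' Cleaning thresholds: at most `max_rounds_per_rater` rounds per rater
#' (default 30), rounds kept only when at least `min_answered_per_round`
#' images were validly answered (default 16, the literal "more than 50% of
#' 30"; set 15 for the lenient reading), images kept only with at least
#' `min_ratings_per_image` ratings (default 8), and a `timeout_s` answer
#' limit (default 25 s).
#'
#' @param max_rounds_per_rater,min_answered_per_round,min_ratings_per_image
#'   Positive integers.
#' @param timeout_s Positive number of seconds.
#' @return A `filter_policy` object.
#' @export
filter_policy <- function(max_rounds_per_rater = 30L,
                          min_answered_per_round = 16L,
                          min_ratings_per_image = 8L,
                          timeout_s = 25) {
  vals <- c(max_rounds_per_rater, min_answered_per_round,
            min_ratings_per_image, timeout_s)
  if (any(vals <= 0)) abort("All filter-policy thresholds must be strictly positive.")
  structure(list(max_rounds_per_rater = as.integer(max_rounds_per_rater),
                 min_answered_per_round = as.integer(min_answered_per_round),
                 min_ratings_per_image = as.integer(min_ratings_per_image),
                 timeout_s = timeout_s),
            class = "filter_policy")
}

#' Confidence policy
#'
#' Whether the intrarater mean answer time used to split high from low
#' confidence is computed per rater overall (default) or per rater and true
#' disease category.
#'
#' @param scope `"per_rater"` or `"per_rater_category"`.
#' @return A `confidence_policy` object.
#' @export
confidence_policy <- function(scope = c("per_rater", "per_rater_category")) {
  structure(list(scope = match.arg(scope)), class = "confidence_policy")
}

#' Drop invalid (timed-out) ratings
#'
#' Timed-out answers carry no diagnosis and are excluded from all analyses.
#'
#' @param ratings Ratings tibble with a logical `valid` column.
#' @return The rows with `valid == TRUE`, order preserved.
#' @export
drop_invalid <- function(ratings) {
  ratings[ratings$valid, , drop = FALSE]
}

#' Cap rounds per rater
#'
#' Keeps, per rater, only the first `max_rounds_per_rater` distinct rounds
#' (ordered by `round_index`), so heavy players cannot dominate the pooled
#' ratings.
#'
#' @param ratings Ratings tibble.
#' @param policy A [filter_policy()].
#' @return Filtered ratings.
#' @export
cap_rounds <- function(ratings, policy = filter_policy()) {
  ratings |>
    dplyr::group_by(.data$rater_id) |>
    dplyr::filter(dplyr::dense_rank(.data$round_index) <=
                    policy$max_rounds_per_rater) |>
    dplyr::ungroup()
}

#' Drop incomplete rounds
#'
#' A (rater, round) group is retained only if its number of valid answers is
#' at least `min_answered_per_round`; complete 30-answer rounds always pass.
#'
#' @param ratings Ratings tibble.
#' @param policy A [filter_policy()].
#' @return Filtered ratings.
#' @export
drop_incomplete_rounds <- function(ratings, policy = filter_policy()) {
  ratings |>
    dplyr::group_by(.data$rater_id, .data$round_index) |>
    dplyr::filter(sum(.data$valid) >= policy$min_answered_per_round) |>
    dplyr::ungroup()
}

#' Select images with enough ratings
#'
#' @param ratings Cleaned ratings tibble.
#' @param policy A [filter_policy()].
#' @return Character vector of `image_id`s with at least
#'   `min_ratings_per_image` ratings.
#' @export
select_rateable_images <- function(ratings, policy = filter_policy()) {
  tab <- table(ratings$image_id)
  names(tab)[tab >= policy$min_ratings_per_image]
}

#' Apply the cleaning filters in pipeline order
#'
#' drop_invalid, cap_rounds, drop_incomplete_rounds, then restriction to
#' rateable images. Row counts before/after each stage are reported via
#' `inform()` and attached as the `"filter_log"` attribute.
#'
#' @param ratings Ratings tibble.
#' @param policy A [filter_policy()].
#' @param verbose Report per-stage row deltas (default TRUE).
#' @return Cleaned ratings tibble with a `filter_log` attribute.
#' @export
apply_filters <- function(ratings, policy = filter_policy(), verbose = TRUE) {
  stages <- list(drop_invalid = function(x) drop_invalid(x),
                 cap_rounds = function(x) cap_rounds(x, policy),
                 drop_incomplete_rounds = function(x) drop_incomplete_rounds(x, policy),
                 select_rateable_images = function(x) {
                   keep <- select_rateable_images(x, policy)
                   x[x$image_id %in% keep, , drop = FALSE]
                 })
  log <- tibble::tibble(stage = character(), rows_before = integer(),
                        rows_after = integer())
  for (nm in names(stages)) {
    before <- nrow(ratings)
    ratings <- stages[[nm]](ratings)
    log <- dplyr::bind_rows(log, tibble::tibble(stage = nm,
                                                rows_before = before,
                                                rows_after = nrow(ratings)))
    if (verbose) {
      inform(sprintf("%s: %d -> %d rows", nm, before, nrow(ratings)))
    }
  }
  attr(ratings, "filter_log") <- log
  ratings
}

#' Label answer confidence from answer times
#'
#' Computes each rater's mean answer time over their valid ratings (or per
#' rater and true category under scope `"per_rater_category"`) and labels a
#' rating high-confidence iff its time is less than or equal to that mean,
#' low otherwise. High and low partition the valid ratings.
#'
#' @param ratings Cleaned ratings tibble (valid rows only).
#' @param policy A [confidence_policy()].
#' @param images Image tibble; required (for the `truth` join) when scope is
#'   `"per_rater_category"` and `ratings` has no `truth` column.
#' @return `ratings` with a `confidence` column (`"high"`/`"low"`).
#' @export
label_confidence <- function(ratings, policy = confidence_policy(),
                             images = NULL) {
  if (any(!ratings$valid)) {
    abort("label_confidence() expects only valid ratings; run drop_invalid() first.")
  }
  if (policy$scope == "per_rater_category" && !"truth" %in% names(ratings)) {
    if (is.null(images)) {
      abort("Scope per_rater_category needs `images` to supply the truth column.")
    }
    ratings <- dplyr::left_join(ratings,
                                images[, c("image_id", "truth")],
                                by = "image_id")
  }
  keys <- if (policy$scope == "per_rater") "rater_id" else c("rater_id", "truth")
  ratings |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(confidence = ifelse(
      .data$answer_time_s <= mean(.data$answer_time_s), "high", "low")) |>
    dplyr::ungroup()
}

#' Unbounded retention
#'
#' Fraction of raters who returned and played on or after day `day` (and
#' within the 100-day observation window) following their registration.
#'
#' @param raters Rater tibble with an `activity_days` list-column of integer
#'   day offsets.
#' @param day Integer in \[0, 100\].
#' @return Proportion in \[0, 1\].
#' @export
unbounded_retention <- function(raters, day) {
  if (nrow(raters) == 0L) abort("Retention is undefined for an empty rater list.")
  if (day < 0 || day > 100) abort("`day` must lie in [0, 100].")
  hits <- vapply(raters$activity_days,
                 function(d) any(d >= day & d <= 100),
                 logical(1))
  mean(hits)
}
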