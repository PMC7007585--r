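# CSV interfaces. All tabular output is UTF-8 CSV with a header row;
# category codes are the 7 uppercase strings; booleans as true/false.
# Analysis outputs carry provenance metadata as leading '#' comment lines.

#' Write a cohort to CSV
#'
#' Writes `raters.csv` (rater_id, experience_group, registration_day,
#' activity_days as semicolon-joined integers), `images.csv` and
#' `ratings.csv` (with the on-disk column name `valid_flag`). Simulation
#' internals (confusion matrices, timing parameters, image distractors) are
#' not serialised; the files carry exactly what a real study would deposit.
#'
#' @param cohort List from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  raters <- tibble::tibble(
    rater_id = cohort$raters$rater_id,
    experience_group = cohort$raters$experience_group,
    registration_day = cohort$raters$registration_day,
    activity_days = vapply(cohort$raters$activity_days,
                           function(d) paste(d, collapse = ";"),
                           character(1)))
  images <- cohort$images[, c("image_id", "truth", "nv_stratum", "difficulty")]
  ratings <- dplyr::rename(cohort$ratings, valid_flag = "valid")
  paths <- file.path(dir, c("raters.csv", "images.csv", "ratings.csv"))
  readr::write_csv(raters, paths[1])
  readr::write_csv(images, paths[2])
  readr::write_csv(ratings, paths[3])
  invisible(paths)
}

#' Read a cohort from CSV
#'
#' Inverse of [write_cohort()] for the analysis-relevant columns.
#'
#' @param dir Directory containing `raters.csv`, `images.csv`,
#'   `ratings.csv`.
#' @return List with tibbles `raters`, `images`, `ratings`.
#' @export
read_cohort <- function(dir) {
  raters <- readr::read_csv(file.path(dir, "raters.csv"),
                            show_col_types = FALSE)
  raters$activity_days <- lapply(strsplit(as.character(raters$activity_days), ";"),
                                 as.integer)
  raters$is_expert <- raters$experience_group == 5L
  images <- readr::read_csv(file.path(dir, "images.csv"),
                            show_col_types = FALSE)
  assert_categories(images$truth)
  images$is_malignant <- images$truth %in% DX_MALIGNANT
  ratings <- readr::read_csv(file.path(dir, "ratings.csv"),
                             show_col_types = FALSE)
  ratings <- dplyr::rename(ratings, valid = "valid_flag")
  assert_categories(ratings$predicted, allow_na = TRUE)
  list(raters = raters, images = images, ratings = ratings)
}

# Write a tibble as CSV preceded by '# key: value' provenance lines
# (readable back with readr::read_csv(comment = "#")).
write_table_with_meta <- function(df, path, meta) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), unlist(meta)), con)
  writeLines(readr::format_csv(df), con, sep = "")
  invisible(path)
}
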