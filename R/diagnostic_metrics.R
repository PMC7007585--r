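# Specific-diagnosis accuracy (7-class), per-category sensitivity, and
# binary malignancy-detection metrics with binomial confidence intervals.

#' Per-image specific accuracy for single raters
#'
#' For every image, the fraction of its answers (within the supplied cell of
#' ratings) exactly equal to the true category. This is the unit later fed
#' to paired comparisons; collectives instead pass through the per-image
#' bootstrap accuracy from [run_collectives()].
#'
#' @param ratings Cleaned valid ratings of one analysis cell.
#' @param images Image tibble (for `truth`), or NULL if `ratings` carries
#'   `truth`.
#' @return Tibble: `image_id`, `truth`, `accuracy`, `n`.
#' @export
per_image_accuracy <- function(ratings, images = NULL) {
  if (!"truth" %in% names(ratings)) {
    if (is.null(images)) abort("Provide `images` or a `truth` column.")
    ratings <- dplyr::inner_join(ratings, images[, c("image_id", "truth")],
                                 by = "image_id")
  }
  ratings |>
    dplyr::group_by(.data$image_id, .data$truth) |>
    dplyr::summarise(accuracy = mean(.data$predicted == .data$truth),
                     n = dplyr::n(), .groups = "drop")
}

#' Mean accuracy over images
#'
#' The primary accuracy metric: the unweighted arithmetic mean of per-image
#' accuracies within a cell. Images with many answers weigh the same as
#' images with few.
#'
#' @param per_image Tibble with an `accuracy` column, one row per image.
#' @return Proportion in \[0, 1\].
#' @export
mean_accuracy <- function(per_image) {
  if (nrow(per_image) == 0L) abort("Mean accuracy is undefined on zero images.")
  mean(per_image$accuracy)
}

#' Per-category sensitivity
#'
#' Mean per-image accuracy restricted to images of one true category: the
#' average probability that an answer (or collective vote) names exactly
#' that category on images that truly are it.
#'
#' @param per_image Tibble from [per_image_accuracy()] (needs `truth`).
#' @param category One of the 7 category codes.
#' @return Proportion in \[0, 1\].
#' @export
category_sensitivity <- function(per_image, category) {
  assert_categories(category)
  sub <- per_image[per_image$truth == category, , drop = FALSE]
  if (nrow(sub) == 0L) {
    abort(sprintf("No images of category %s in this cell.", category))
  }
  mean(sub$accuracy)
}

#' Per-category sensitivity table
#'
#' @param per_image Tibble from [per_image_accuracy()].
#' @return Tibble: `truth`, `sensitivity`, `n_images`.
#' @export
category_sensitivity_table <- function(per_image) {
  per_image |>
    dplyr::group_by(truth = .data$truth) |>
    dplyr::summarise(sensitivity = mean(.data$accuracy),
                     n_images = dplyr::n(), .groups = "drop")
}

#' Binary malignancy counts
#'
#' @param tp,fp,tn,fn Nonnegative counts (fractional counts are allowed for
#'   expected counts of bootstrap votes).
#' @return A `binary_counts` object.
#' @export
binary_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0)) abort("Binary counts must be nonnegative.")
  structure(as.list(v), class = "binary_counts")
}

#' Collapse predictions to malignancy-detection counts
#'
#' A prediction is positive iff it names any malignant category (AKIEC, BCC
#' or MEL); the truth is positive iff the image is malignant. Predicting BCC
#' on a MEL image is therefore a true positive, even though it is wrong as a
#' specific diagnosis.
#'
#' @param predicted,truth Character vectors of category codes, same length.
#' @return A [binary_counts()] object; `tp+fp+tn+fn` equals the number of
#'   classified answers.
#' @export
#' @examples
#' binarize_malignancy(c("BCC", "NV", "VASC"), c("MEL", "MEL", "BKL"))
binarize_malignancy <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  pp <- is_malignant(predicted)
  tp_ <- is_malignant(truth)
  keep <- !is.na(pp)
  pp <- pp[keep]
  tp_ <- tp_[keep]
  binary_counts(tp = sum(pp & tp_), fp = sum(pp & !tp_),
                tn = sum(!pp & !tp_), fn = sum(!pp & tp_))
}

#' Expected malignancy counts from per-image vote probabilities
#'
#' For bootstrapped collectives each image contributes its expected vote:
#' probability `p_malignant` of a malignant collective vote. Counts are the
#' sums of these probabilities (one expected vote per image).
#'
#' @param p_malignant Numeric vector of per-image malignant-vote
#'   probabilities.
#' @param truth_malignant Logical vector, same length.
#' @return A [binary_counts()] object with fractional entries.
#' @export
binarize_malignancy_rates <- function(p_malignant, truth_malignant) {
  stopifnot(length(p_malignant) == length(truth_malignant))
  binary_counts(tp = sum(p_malignant[truth_malignant]),
                fn = sum(1 - p_malignant[truth_malignant]),
                fp = sum(p_malignant[!truth_malignant]),
                tn = sum(1 - p_malignant[!truth_malignant]))
}

ci_wilson <- function(x, n, conf_level) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  centre <- (x + z^2 / 2) / (n + z^2)
  half <- z * sqrt(x * (n - x) / n + z^2 / 4) / (n + z^2)
  c(centre - half, centre + half)
}

ci_clopper_pearson <- function(x, n, conf_level) {
  a <- (1 - conf_level) / 2
  lower <- if (x <= 0) 0 else qbeta(a, x, n - x + 1)
  upper <- if (x >= n) 1 else qbeta(1 - a, x + 1, n - x)
  c(lower, upper)
}

ci_normal <- function(x, n, conf_level) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  half <- z * sqrt(p * (1 - p) / n)
  c(max(0, p - half), min(1, p + half))
}

#' Diagnostic summary from binary counts
#'
#' Standard formulas: sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`,
#' PPV `tp/(tp+fp)`, NPV `tn/(tn+fn)`, each with a binomial confidence
#' interval. A metric with a zero denominator is reported as `NA` with a
#' warning, never as 0.
#'
#' @param counts A [binary_counts()] object.
#' @param ci_method `"wilson"` (default), `"clopper-pearson"` or
#'   `"normal"`.
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble: `metric`, `estimate`, `lower`, `upper`, `x`, `n`.
#' @export
#' @examples
#' binary_metrics(binary_counts(tp = 8, fp = 1, tn = 9, fn = 2))
binary_metrics <- function(counts,
                           ci_method = c("wilson", "clopper-pearson", "normal"),
                           conf_level = 0.95) {
  stopifnot(inherits(counts, "binary_counts"))
  ci_method <- match.arg(ci_method)
  ci_fun <- switch(ci_method,
                   wilson = ci_wilson,
                   `clopper-pearson` = ci_clopper_pearson,
                   normal = ci_normal)
  spec <- list(sensitivity = c("tp", "fn"),
               specificity = c("tn", "fp"),
               ppv = c("tp", "fp"),
               npv = c("tn", "fn"))
  rows <- lapply(names(spec), function(metric) {
    x <- counts[[spec[[metric]][1]]]
    n <- x + counts[[spec[[metric]][2]]]
    if (n <= 0) {
      warn(sprintf("%s undefined: zero denominator.", metric))
      return(tibble::tibble(metric = metric, estimate = NA_real_,
                            lower = NA_real_, upper = NA_real_,
                            x = x, n = n))
    }
    ci <- ci_fun(x, n, conf_level)
    tibble::tibble(metric = metric, estimate = x / n,
                   lower = max(0, ci[1]), upper = min(1, ci[2]),
                   x = x, n = n)
  })
  dplyr::bind_rows(rows)
}
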