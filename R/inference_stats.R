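# Paired comparison of per-image accuracy between analysis cells, with
# Holm-corrected p values and mean-difference confidence intervals.

#' Join two cells on overlapping images
#'
#' Inner join of two per-image accuracy tables on `image_id`; images seen in
#' only one cell are excluded (their count is attached as the
#' `"n_excluded"` attribute).
#'
#' @param cell_a,cell_b Tibbles with `image_id` and `accuracy`.
#' @return Paired tibble with `accuracy_a`, `accuracy_b`.
#' @export
overlap_join <- function(cell_a, cell_b) {
  pairs <- dplyr::inner_join(
    cell_a[, c("image_id", "accuracy")],
    cell_b[, c("image_id", "accuracy")],
    by = "image_id", suffix = c("_a", "_b"))
  attr(pairs, "n_excluded") <-
    nrow(cell_a) + nrow(cell_b) - 2L * nrow(pairs)
  pairs
}

#' Paired t test on per-image accuracy differences
#'
#' Two-sided paired t test of `accuracy_b - accuracy_a` over overlapping
#' images. The mean difference and its 95% CI are reported in percentage
#' points. With zero variance of the differences the mean difference is
#' still reported but the t statistic and p value are `NA` (degenerate CI).
#'
#' @param pairs Tibble from [overlap_join()].
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `n_images`, `mean_difference`, `ci_lower`,
#'   `ci_upper` (percentage points), `t_statistic`, `df`, `p_raw`.
#' @export
paired_t <- function(pairs, conf_level = 0.95) {
  n <- nrow(pairs)
  if (n < 2L) {
    abort("Paired comparison needs at least 2 overlapping images.",
          class = "crowddx_not_computable")
  }
  d <- pairs$accuracy_b - pairs$accuracy_a
  if (sd(d) == 0) {
    warn("Zero variance of paired differences; p value undefined.")
    return(tibble::tibble(n_images = n, mean_difference = mean(d) * 100,
                          ci_lower = mean(d) * 100, ci_upper = mean(d) * 100,
                          t_statistic = NA_real_, df = n - 1L,
                          p_raw = NA_real_))
  }
  tt <- stats::t.test(d, conf.level = conf_level)
  tibble::tibble(n_images = n,
                 mean_difference = mean(d) * 100,
                 ci_lower = tt$conf.int[1] * 100,
                 ci_upper = tt$conf.int[2] * 100,
                 t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_raw = tt$p.value)
}

#' Holm step-down adjustment
#'
#' Bonferroni–Holm family-wise error rate correction; adjusted values are
#' elementwise at least the raw values and preserve their ranking. `NA`
#' entries (non-computable tests) pass through and do not count toward the
#' family size.
#'
#' @param p Numeric vector of raw p values in \[0, 1\] (NA allowed).
#' @return Adjusted p values in the original order.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04))
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p values must lie in [0, 1].")
  stats::p.adjust(p, method = "holm")
}

#' Compare analysis cells against a baseline
#'
#' Builds the pairwise family: every non-baseline cell is compared with the
#' baseline cell by a paired t test over their overlapping images, and p
#' values are Holm-adjusted over the family. The baseline appears first,
#' marked `reference = TRUE`, with zero self-difference.
#'
#' @param cells Named list of per-image accuracy tibbles; each element must
#'   carry attributes-free columns `image_id`, `accuracy`.
#' @param cell_info Tibble with one row per cell (same order/names as
#'   `cells`): columns `label`, `group`, `k` (NA = single raters),
#'   `confidence`.
#' @param baseline Name (label) of the baseline cell.
#' @param alpha Significance level recorded on the output (default 0.05).
#' @return Comparisons tibble: cell metadata, `mean_accuracy`, `n_images`,
#'   `mean_difference`, `ci_lower`, `ci_upper`, `t_statistic`, `p_raw`,
#'   `p_adjusted`, `significant`, `reference`.
#' @export
compare_to_baseline <- function(cells, cell_info, baseline, alpha = 0.05) {
  stopifnot(length(cells) == nrow(cell_info),
            identical(names(cells), cell_info$label))
  if (!baseline %in% cell_info$label) {
    abort(sprintf("Baseline cell '%s' not among the cells.", baseline))
  }
  base <- cells[[baseline]]
  rows <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    label <- cell_info$label[i]
    info <- cell_info[i, ]
    macc <- mean_accuracy(cells[[label]])
    if (label == baseline) {
      rows[[i]] <- dplyr::bind_cols(info, tibble::tibble(
        mean_accuracy = macc * 100, n_images = nrow(base),
        mean_difference = 0, ci_lower = NA_real_, ci_upper = NA_real_,
        t_statistic = NA_real_, p_raw = NA_real_, reference = TRUE))
      next
    }
    pairs <- overlap_join(base, cells[[label]])
    res <- tryCatch(paired_t(pairs),
                    crowddx_not_computable = function(e) {
                      tibble::tibble(n_images = nrow(pairs),
                                     mean_difference = NA_real_,
                                     ci_lower = NA_real_, ci_upper = NA_real_,
                                     t_statistic = NA_real_, df = NA_real_,
                                     p_raw = NA_real_)
                    })
    rows[[i]] <- dplyr::bind_cols(info, tibble::tibble(
      mean_accuracy = macc * 100, n_images = res$n_images,
      mean_difference = res$mean_difference,
      ci_lower = res$ci_lower, ci_upper = res$ci_upper,
      t_statistic = res$t_statistic, p_raw = res$p_raw, reference = FALSE))
  }
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- holm_adjust(out$p_raw)
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out
}
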