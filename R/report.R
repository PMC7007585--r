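# Human-readable report rendering and the per-category sensitivity figure.

fmt_pct <- function(x, digits = 2) {
  ifelse(is.na(x), "-", formatC(x, format = "f", digits = digits))
}

md_table <- function(df) {
  cells <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Render a markdown summary report
#'
#' Writes the accuracy-comparison table (cells vs the single-nonexpert
#' baseline), the malignancy-detection diagnostic values, and the
#' per-category sensitivity series, with provenance (seed, config hash,
#' package version) in the header.
#'
#' @param analysis List from [analyze_cohort()].
#' @param config The [pipeline_config()] used.
#' @param path Output file path (markdown).
#' @return Invisibly, `path`.
#' @export
render_report <- function(analysis, config, path) {
  meta <- provenance_meta(config)
  cmp <- analysis$comparisons
  cmp_tab <- tibble::tibble(
    Experience = cmp$group,
    `Collective size` = ifelse(is.na(cmp$k), "-", as.character(cmp$k)),
    Confidence = cmp$confidence,
    `Mean accuracy, %` = fmt_pct(cmp$mean_accuracy),
    `Mean difference (95% CI)` = ifelse(
      cmp$reference, "Reference",
      sprintf("%s (%s to %s)", fmt_pct(cmp$mean_difference),
              fmt_pct(cmp$ci_lower), fmt_pct(cmp$ci_upper))),
    `Adjusted p` = ifelse(cmp$reference, "Reference",
                          ifelse(is.na(cmp$p_adjusted), "-",
                                 format.pval(cmp$p_adjusted, digits = 3,
                                             eps = 0.001))))
  ms <- analysis$metrics_summary |>
    tidyr::pivot_wider(id_cols = c("group", "k", "confidence"),
                       names_from = "metric",
                       values_from = c("estimate", "lower", "upper"))
  ms_tab <- tibble::tibble(
    Experience = ms$group,
    `Collective size` = ifelse(is.na(ms$k), "-", as.character(ms$k)),
    Confidence = ms$confidence,
    `Sensitivity, % (95% CI)` = sprintf(
      "%s (%s to %s)", fmt_pct(ms$estimate_sensitivity * 100, 1),
      fmt_pct(ms$lower_sensitivity * 100, 1), fmt_pct(ms$upper_sensitivity * 100, 1)),
    `Specificity, % (95% CI)` = sprintf(
      "%s (%s to %s)", fmt_pct(ms$estimate_specificity * 100, 1),
      fmt_pct(ms$lower_specificity * 100, 1), fmt_pct(ms$upper_specificity * 100, 1)),
    `PPV, % (95% CI)` = sprintf(
      "%s (%s to %s)", fmt_pct(ms$estimate_ppv * 100, 1),
      fmt_pct(ms$lower_ppv * 100, 1), fmt_pct(ms$upper_ppv * 100, 1)),
    `NPV, % (95% CI)` = sprintf(
      "%s (%s to %s)", fmt_pct(ms$estimate_npv * 100, 1),
      fmt_pct(ms$lower_npv * 100, 1), fmt_pct(ms$upper_npv * 100, 1)))
  sens <- analysis$category_sensitivity
  sens$cell <- cell_label(sens$group, sens$k, sens$confidence)
  sens_all <- sens[sens$confidence == "all", , drop = FALSE]
  sens_tab <- tidyr::pivot_wider(
    sens_all[, c("truth", "cell", "sensitivity")],
    names_from = "cell", values_from = "sensitivity",
    values_fn = function(x) round(100 * x, 1))

  lines <- c(
    "# Collective diagnosis analysis report",
    "",
    sprintf("- package: %s", meta$package),
    sprintf("- seed: %s", meta$seed),
    sprintf("- config hash: %s", meta$config_hash),
    "",
    "## Mean specific accuracy vs single nonexperts (paired t, Holm-adjusted)",
    "",
    md_table(cmp_tab),
    "",
    "## Malignancy detection (pooled diagnostic values)",
    "",
    md_table(ms_tab),
    "",
    "## Per-category sensitivity (confidence: all), %",
    "",
    md_table(sens_tab),
    "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Plot per-category sensitivity against collective size
#'
#' Line-and-dot series of mean per-category sensitivity of nonexpert
#' collectives over the collective sizes, with horizontal reference lines
#' for single nonexperts and single experts.
#'
#' @param category_sensitivity Tibble from [analyze_cohort()].
#' @return A ggplot object.
#' @export
plot_category_sensitivity <- function(category_sensitivity) {
  df <- category_sensitivity[category_sensitivity$confidence == "all", ,
                             drop = FALSE]
  coll <- df[!is.na(df$k) & df$group == "nonexpert", , drop = FALSE]
  singles <- df[is.na(df$k), , drop = FALSE]
  ggplot2::ggplot(coll, ggplot2::aes(x = .data$k, y = .data$sensitivity)) +
    ggplot2::geom_hline(
      data = singles,
      ggplot2::aes(yintercept = .data$sensitivity, linetype = .data$group),
      colour = "grey40") +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point(colour = "#2c7fb8") +
    ggplot2::facet_wrap(~truth, nrow = 2) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "Collective size", y = "Mean sensitivity",
                  linetype = "Single raters") +
    ggplot2::theme_minimal()
}
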