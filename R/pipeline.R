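# End-to-end pipeline: simulate -> clean -> label confidence -> collectives
# -> metrics -> paired comparisons, with provenance on every output.

#' Pipeline configuration
#'
#' Bundles the nested configurations of every stage. `seed` overrides the
#' seeds of the simulation and collective stages (the collective stage uses
#' `seed + 3` so its draws are independent of the generator's streams).
#'
#' @param seed Master seed, or NULL to keep the nested seeds.
#' @param simulation A [simulation_config()].
#' @param filters A [filter_policy()].
#' @param confidence A [confidence_policy()].
#' @param collective A [collective_config()].
#' @param comparison_sizes Collective sizes entering the paired-comparison
#'   family (default `c(4, 8)`; the full `collective$sizes` still feed the
#'   per-category sensitivity series).
#' @param ci_method Binomial CI method for diagnostic values.
#' @param alpha Two-sided significance level (default 0.05).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(seed = NULL,
                            simulation = simulation_config(),
                            filters = filter_policy(),
                            confidence = confidence_policy(),
                            collective = collective_config(),
                            comparison_sizes = c(4L, 8L),
                            ci_method = c("wilson", "clopper-pearson", "normal"),
                            alpha = 0.05) {
  if (!is.null(seed)) {
    simulation$seed <- as.integer(seed)
    collective$seed <- as.integer(seed) + 3L
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  structure(list(simulation = simulation, filters = filters,
                 confidence = confidence, collective = collective,
                 comparison_sizes = as.integer(comparison_sizes),
                 ci_method = match.arg(ci_method), alpha = alpha),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML/JSON
#'
#' Reads a single document whose top-level keys (`simulation`, `filters`,
#' `confidence`, `collective`, `comparison_sizes`, `ci_method`, `alpha`,
#' `seed`) override the corresponding defaults. A seed must be present
#' either at top level or in `simulation`.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  fix_named <- function(x) {
    if (is.list(x)) unlist(x) else x
  }
  sim_args <- raw$simulation %||% list()
  for (nm in c("n_raters_per_group", "n_images_per_category",
               "group_accuracy", "group_log_time")) {
    if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- fix_named(sim_args[[nm]])
  }
  simulation <- do.call(simulation_config, sim_args)
  filters <- do.call(filter_policy, raw$filters %||% list())
  confidence <- do.call(confidence_policy, raw$confidence %||% list())
  collective <- do.call(collective_config, raw$collective %||% list())
  pipeline_config(seed = raw$seed,
                  simulation = simulation, filters = filters,
                  confidence = confidence, collective = collective,
                  comparison_sizes = raw$comparison_sizes %||% c(4L, 8L),
                  ci_method = raw$ci_method %||% "wilson",
                  alpha = raw$alpha %||% 0.05)
}

cell_label <- function(group, k, confidence) {
  sprintf("%s|%s|%s", group, ifelse(is.na(k), "single", k), confidence)
}

#' Analyse a cohort
#'
#' Runs the full analysis on a (simulated or imported) cohort: cleaning
#' filters in fixed order, confidence labelling, bootstrap collectives of
#' the configured sizes for nonexpert answers in each confidence stratum,
#' per-category sensitivities, pooled malignancy-detection metrics, and the
#' paired-comparison family against the single-nonexpert baseline with Holm
#' correction.
#'
#' @param cohort List with `raters`, `images`, `ratings`.
#' @param config A [pipeline_config()].
#' @param verbose Log filter deltas and exclusions (default TRUE).
#' @return List of tibbles: `comparisons`, `metrics_summary`,
#'   `category_sensitivity`, `collective_accuracy`, plus `cells` (the
#'   per-image accuracy tables) and `filter_log`.
#' @export
analyze_cohort <- function(cohort, config = pipeline_config(),
                           verbose = TRUE) {
  ratings <- apply_filters(cohort$ratings, config$filters, verbose = verbose)
  filter_log <- attr(ratings, "filter_log")
  if (nrow(ratings) == 0L) {
    abort("No ratings survive the cleaning filters.")
  }
  ratings <- dplyr::inner_join(
    ratings,
    cohort$images[, c("image_id", "truth", "is_malignant")],
    by = "image_id")
  ratings <- label_confidence(ratings, config$confidence)
  groups <- cohort$raters[, c("rater_id", "experience_group")]
  groups$group <- ifelse(groups$experience_group == 5L, "expert", "nonexpert")
  ratings <- dplyr::inner_join(ratings, groups[, c("rater_id", "group")],
                               by = "rater_id")

  conf_subset <- function(df, conf) {
    if (conf == "all") df else df[df$confidence == conf, , drop = FALSE]
  }

  cells <- list()
  cell_info <- list()
  add_cell <- function(per_image, group, k, confidence) {
    label <- cell_label(group, k, confidence)
    cells[[label]] <<- per_image
    cell_info[[label]] <<- tibble::tibble(label = label, group = group,
                                          k = k, confidence = confidence)
  }

  # Single-rater cells (both groups, three confidence strata).
  single_pools <- list()
  for (grp in c("nonexpert", "expert")) {
    for (conf in c("all", "high", "low")) {
      sub <- conf_subset(ratings[ratings$group == grp, , drop = FALSE], conf)
      if (nrow(sub) == 0L) next
      single_pools[[cell_label(grp, NA, conf)]] <- sub
      add_cell(per_image_accuracy(sub), grp, NA_integer_, conf)
    }
  }

  # Nonexpert collectives per confidence stratum.
  collective_rows <- list()
  for (conf in c("all", "high", "low")) {
    sub <- conf_subset(ratings[ratings$group == "nonexpert", , drop = FALSE],
                       conf)
    if (nrow(sub) == 0L) next
    sets <- image_answer_sets(sub)
    cc <- config$collective
    cc$seed <- cc$seed + match(conf, c("all", "high", "low"))
    res <- run_collectives(sets, cc, verbose = verbose)
    if (nrow(res) == 0L) next
    res$group <- "nonexpert"
    res$confidence <- conf
    collective_rows[[conf]] <- res
    for (k in cc$sizes) {
      sub_k <- res[res$k == k, , drop = FALSE]
      if (nrow(sub_k) < 1L) next
      add_cell(sub_k[, c("image_id", "truth", "accuracy", "n_answers")],
               "nonexpert", k, conf)
    }
  }
  collective_accuracy <- dplyr::bind_rows(collective_rows)

  # Per-category sensitivity series (confidence "all"): single groups and
  # every nonexpert collective size.
  sens_rows <- list()
  for (label in names(cells)) {
    info <- cell_info[[label]]
    tab <- category_sensitivity_table(cells[[label]])
    tab$group <- info$group
    tab$k <- info$k
    tab$confidence <- info$confidence
    sens_rows[[label]] <- tab
  }
  category_sensitivity <- dplyr::bind_rows(sens_rows)

  # Pooled malignancy-detection metrics per cell: single cells pool answers,
  # collective cells pool expected votes (one per image).
  metric_rows <- list()
  for (label in names(cells)) {
    info <- cell_info[[label]]
    counts <- if (is.na(info$k)) {
      pool <- single_pools[[label]]
      binarize_malignancy(pool$predicted, pool$truth)
    } else {
      sub_k <- collective_accuracy[
        collective_accuracy$k == info$k &
          collective_accuracy$confidence == info$confidence, , drop = FALSE]
      binarize_malignancy_rates(sub_k$p_malignant,
                                sub_k$truth %in% DX_MALIGNANT)
    }
    bm <- binary_metrics(counts, ci_method = config$ci_method)
    bm$label <- label
    bm$group <- info$group
    bm$k <- info$k
    bm$confidence <- info$confidence
    metric_rows[[label]] <- bm
  }
  metrics_summary <- dplyr::bind_rows(metric_rows)

  # Paired-comparison family vs the single-nonexpert-all baseline.
  baseline <- cell_label("nonexpert", NA, "all")
  family <- c(baseline,
              cell_label("nonexpert", NA, c("low", "high")),
              unlist(lapply(intersect(config$comparison_sizes,
                                      config$collective$sizes),
                            function(k) cell_label("nonexpert", k,
                                                   c("all", "low", "high")))),
              cell_label("expert", NA, c("all", "low", "high")))
  family <- family[family %in% names(cells)]
  comparisons <- compare_to_baseline(
    cells[family],
    dplyr::bind_rows(cell_info[family]),
    baseline = baseline,
    alpha = config$alpha)

  list(comparisons = comparisons,
       metrics_summary = metrics_summary,
       category_sensitivity = category_sensitivity,
       collective_accuracy = collective_accuracy,
       cells = cells,
       filter_log = filter_log)
}

provenance_meta <- function(config) {
  list(package = paste0("crowddx ", as.character(utils::packageVersion("crowddx"))),
       seed = config$simulation$seed,
       config_hash = rlang::hash(config))
}

#' Run the full pipeline and write all outputs
#'
#' Simulates a cohort, writes it to CSV, analyses it, writes the four
#' analysis tables (each with provenance comment headers), a manifest JSON
#' and a markdown report to `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param verbose Log progress (default TRUE).
#' @return Invisibly, the analysis list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config$simulation)
  write_cohort(cohort, out_dir)
  analysis <- analyze_cohort(cohort, config, verbose = verbose)
  meta <- provenance_meta(config)
  for (nm in c("comparisons", "metrics_summary", "category_sensitivity",
               "collective_accuracy")) {
    write_table_with_meta(analysis[[nm]],
                          file.path(out_dir, paste0(nm, ".csv")), meta)
  }
  manifest <- c(meta, list(
    n_raters = nrow(cohort$raters),
    n_images = nrow(cohort$images),
    n_ratings = nrow(cohort$ratings),
    n_ratings_clean = sum(analysis$filter_log$rows_after[
      analysis$filter_log$stage == "select_rateable_images"])))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  render_report(analysis, config, file.path(out_dir, "report.md"))
  invisible(analysis)
}
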