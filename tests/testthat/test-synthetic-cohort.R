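test_that("generate_raters books the requested cohort and is deterministic", {
  cfg <- simulation_config(n_raters_per_group = c(`1` = 2L, `5` = 1L),
                           seed = 3L)
  raters <- generate_raters(cfg)
  expect_equal(nrow(raters), 3L)
  expect_equal(sum(raters$is_expert), 1L)
  expect_true(all(raters$is_expert == (raters$experience_group == 5L)))
  again <- generate_raters(cfg)
  expect_identical(raters, again)
})

test_that("rater profiles are valid: stochastic rows, activity on day 0", {
  raters <- generate_raters(small_sim_config())
  for (i in seq_len(nrow(raters))) {
    cm <- raters$confusion[[i]]
    expect_equal(unname(rowSums(cm)), rep(1, 7), tolerance = 1e-9)
    expect_true(all(cm >= 0 & cm <= 1))
    if (raters$n_rounds[i] > 0L) {
      expect_true(0L %in% raters$activity_days[[i]])
    }
  }
})

test_that("experts carry more diagonal mass than nonexperts on average", {
  cfg <- simulation_config(n_raters_per_group = c(`1` = 30L, `2` = 30L,
                                                  `3` = 30L, `4` = 30L,
                                                  `5` = 30L),
                           seed = 5L)
  raters <- generate_raters(cfg)
  diag_mass <- vapply(raters$confusion, function(m) mean(diag(m)), numeric(1))
  expect_gt(mean(diag_mass[raters$is_expert]),
            mean(diag_mass[!raters$is_expert]))
})

test_that("sample_batch reproduces the blueprint composition", {
  pool <- make_pool()
  set.seed(9)
  batch <- sample_batch(pool)
  expect_equal(nrow(batch), 30L)
  counts <- table(factor(batch$truth, levels = diagnosis_categories()))
  expect_equal(as.integer(counts), c(3L, 4L, 4L, 3L, 5L, 9L, 2L))
  nv <- batch[batch$truth == "NV", ]
  expect_equal(sort(as.integer(table(nv$nv_stratum))), c(3L, 3L, 3L))
  expect_equal(anyDuplicated(batch$image_id), 0L)
})

test_that("sample_batch errors name the exhausted category", {
  pool <- make_pool()
  pool <- pool[!(pool$truth == "DF" & seq_len(nrow(pool)) %in%
                   head(which(pool$truth == "DF"), 10)), ]
  set.seed(1)
  expect_error(sample_batch(pool), class = "crowddx_pool_exhausted")
  expect_error(sample_batch(pool), regexp = "DF")
})

test_that("simulate_ratings honours round counts, timing bounds, determinism", {
  cfg <- small_sim_config(seed = 21L, timeout_rate = 0,
                          incomplete_round_rate = 0)
  raters <- generate_raters(cfg)
  raters <- raters[1, ]
  raters$n_rounds <- 2L
  images <- generate_images(cfg)
  ratings <- simulate_ratings(raters, images, config = cfg)
  expect_equal(nrow(ratings), 60L)
  expect_true(all(ratings$valid))
  expect_true(all(ratings$answer_time_s > 0 & ratings$answer_time_s <= 25))
  again <- simulate_ratings(raters, images, config = cfg)
  expect_identical(ratings, again)
})

test_that("timeouts are emitted as invalid ratings at the time limit", {
  cfg <- small_sim_config(seed = 8L, timeout_rate = 0.3)
  co <- simulate_cohort(cfg)
  invalid <- co$ratings[!co$ratings$valid, ]
  expect_gt(nrow(invalid), 0L)
  expect_true(all(is.na(invalid$predicted)))
  expect_true(all(invalid$answer_time_s == 25))
  expect_true(all(!is.na(co$ratings$predicted[co$ratings$valid])))
})

test_that("every complete round matches the blueprint composition", {
  cfg <- small_sim_config(seed = 13L, timeout_rate = 0,
                          incomplete_round_rate = 0.3)
  co <- simulate_cohort(cfg)
  joined <- dplyr::inner_join(co$ratings,
                              co$images[, c("image_id", "truth")],
                              by = "image_id")
  per_round <- dplyr::count(joined, rater_id, round_index)
  complete <- dplyr::semi_join(joined, per_round[per_round$n == 30L, ],
                               by = c("rater_id", "round_index"))
  comp <- dplyr::count(complete, rater_id, round_index, truth)
  expected <- c(AKIEC = 3L, BCC = 4L, BKL = 4L, DF = 3L, MEL = 5L,
                NV = 9L, VASC = 2L)
  expect_true(all(comp$n == expected[comp$truth]))
  # and some rounds really were truncated
  expect_gt(sum(per_round$n < 30L), 0L)
})

test_that("generator calibrates to the configured confusion diagonal", {
  # difficulty 0 and a degenerate confident state: per-category accuracy
  # must converge to the (possibly boosted) diagonal.
  for (cf in c(0, 1)) {
    cfg <- simulation_config(
      n_raters_per_group = c(`3` = 16L),
      n_images_per_category = c(AKIEC = 4L, BCC = 5L, BKL = 6L, DF = 4L,
                                MEL = 6L, NV = 9L, VASC = 3L),
      accuracy_sd = 0, difficulty_mean = 0, difficulty_spread = 0,
      confident_fraction = cf, timeout_rate = 0,
      incomplete_round_rate = 0,
      rounds_distribution = list(mean = 25, heavy_prob = 0, heavy_mean = 25),
      seed = 31L + cf)
    co <- simulate_cohort(cfg)
    joined <- dplyr::inner_join(co$ratings,
                                co$images[, c("image_id", "truth")],
                                by = "image_id")
    diag_cfg <- cfg$group_accuracy[["3"]]
    if (cf == 1) diag_cfg <- 1 - (1 - diag_cfg) / cfg$confident_accuracy_boost
    n <- nrow(joined)
    expect_gt(n, 10000)
    p_hat <- mean(joined$predicted == joined$truth)
    se <- sqrt(diag_cfg * (1 - diag_cfg) / n)
    expect_lt(abs(p_hat - diag_cfg), 3 * se)
  }
})

test_that("confident (fast) answers are more accurate than slow ones", {
  cfg <- simulation_config(n_raters_per_group = c(`2` = 8L),
                           confident_accuracy_boost = 1.4,
                           rounds_distribution = list(mean = 15,
                                                      heavy_prob = 0,
                                                      heavy_mean = 25),
                           seed = 17L)
  co <- simulate_cohort(cfg)
  ratings <- drop_invalid(co$ratings)
  ratings <- label_confidence(ratings)
  joined <- dplyr::inner_join(ratings, co$images[, c("image_id", "truth")],
                              by = "image_id")
  acc <- tapply(joined$predicted == joined$truth, joined$confidence, mean)
  expect_gt(acc[["high"]], acc[["low"]])
})

test_that("cohort CSV round-trip preserves the analysis columns", {
  cfg <- small_sim_config(seed = 19L)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$ratings$predicted, co$ratings$predicted)
  expect_equal(back$ratings$valid, co$ratings$valid)
  expect_equal(back$images$truth, co$images$truth)
  expect_equal(back$raters$activity_days, co$raters$activity_days)
  expect_equal(back$images$is_malignant, co$images$is_malignant)
})
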