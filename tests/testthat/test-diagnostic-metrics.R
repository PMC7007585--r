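test_that("per-image accuracy is the fraction of exactly-correct answers", {
  r <- make_ratings("R1", rep("A", 4), 1:4,
                    predicted = c("MEL", "MEL", "NV", "BKL"))
  images <- tibble::tibble(image_id = "A", truth = "MEL")
  out <- per_image_accuracy(r, images)
  expect_equal(out$accuracy, 0.5)
  expect_equal(out$n, 4L)
  # a malignant-but-wrong specific prediction is incorrect here
  r2 <- make_ratings("R1", "A", 1, predicted = "BCC")
  expect_equal(per_image_accuracy(r2, images)$accuracy, 0)
  r3 <- make_ratings("R1", "A", 1:3, predicted = "MEL")
  expect_equal(per_image_accuracy(r3, images)$accuracy, 1)
})

test_that("mean accuracy weights images equally regardless of answer counts", {
  per_image <- tibble::tibble(
    image_id = c("A", "B"), truth = "MEL",
    accuracy = c(1, 0), n = c(100L, 2L))
  expect_equal(mean_accuracy(per_image), 0.5)
  # contrast: the answer-weighted mean would be 100/102
  expect_false(isTRUE(all.equal(mean_accuracy(per_image), 100 / 102)))
  expect_equal(mean_accuracy(per_image[1, ]), 1)
  expect_error(mean_accuracy(per_image[0, ]), "zero images")
  expect_gte(mean_accuracy(per_image), min(per_image$accuracy))
  expect_lte(mean_accuracy(per_image), max(per_image$accuracy))
})

test_that("category sensitivity scores the specific diagnosis, not malignancy", {
  per_image <- tibble::tibble(
    image_id = c("A", "B", "C"),
    truth = c("MEL", "MEL", "NV"),
    accuracy = c(1, 1, 0.5), n = 3L)
  expect_equal(category_sensitivity(per_image, "MEL"), 1)
  # MEL images all voted BCC: malignancy correct, specific sensitivity 0
  per_image$accuracy <- c(0, 0, 0.5)
  expect_equal(category_sensitivity(per_image, "MEL"), 0)
  expect_error(category_sensitivity(per_image, "DF"), "No images")
  tab <- category_sensitivity_table(per_image)
  expect_equal(tab$sensitivity[tab$truth == "NV"], 0.5)
})

test_that("malignancy binarisation follows the malignant-set rule", {
  counts <- binarize_malignancy(c("BCC", "NV", "VASC", "AKIEC"),
                                c("MEL", "MEL", "BKL", "NV"))
  expect_equal(counts$tp, 1) # BCC on MEL: correct malignancy detection
  expect_equal(counts$fn, 1) # NV on MEL
  expect_equal(counts$tn, 1) # VASC on BKL
  expect_equal(counts$fp, 1) # AKIEC on NV
  expect_equal(counts$tp + counts$fp + counts$tn + counts$fn, 4)
  # fractional expected-vote counts conserve the number of images
  frac <- binarize_malignancy_rates(c(0.8, 0.3), c(TRUE, FALSE))
  expect_equal(frac$tp + frac$fp + frac$tn + frac$fn, 2)
  expect_equal(frac$tp, 0.8)
  expect_equal(frac$fp, 0.3)
})

test_that("binary metrics apply the standard formulas with binomial CIs", {
  counts <- binary_counts(tp = 8, fn = 2, tn = 9, fp = 1)
  out <- binary_metrics(counts)
  est <- setNames(out$estimate, out$metric)
  expect_equal(unname(est["sensitivity"]), 0.8)
  expect_equal(unname(est["specificity"]), 0.9)
  expect_equal(unname(est["ppv"]), 8 / 9, tolerance = 1e-12)
  expect_equal(unname(est["npv"]), 9 / 11, tolerance = 1e-12)
  sym <- binary_metrics(binary_counts(5, 5, 5, 5))
  expect_equal(sym$estimate, rep(0.5, 4))
  expect_true(all(out$lower <= out$estimate & out$estimate <= out$upper))
})

test_that("interval methods agree with reference implementations", {
  # Wilson: prop.test without continuity correction
  wilson <- crowddx:::ci_wilson(8, 10, 0.95)
  ref <- stats::prop.test(8, 10, correct = FALSE)$conf.int
  expect_equal(wilson, as.numeric(ref), tolerance = 1e-9)
  # Clopper-Pearson: binom.test
  cp <- crowddx:::ci_clopper_pearson(8, 10, 0.95)
  refb <- stats::binom.test(8, 10)$conf.int
  expect_equal(cp, as.numeric(refb), tolerance = 1e-9)
  # zero denominators are NA with a warning, not zero
  expect_warning(und <- binary_metrics(binary_counts(tp = 0, fp = 0, tn = 3,
                                                     fn = 2)), "ppv")
  expect_true(is.na(und$estimate[und$metric == "ppv"]))
})

test_that("specific accuracy never exceeds malignancy accuracy on malignant images", {
  set.seed(33)
  for (i in 1:20) {
    truth <- sample(malignant_categories(), 1)
    answers <- sample(diagnosis_categories(), 12, replace = TRUE)
    specific <- mean(answers == truth)
    binary <- mean(answers %in% malignant_categories())
    expect_lte(specific, binary)
  }
})

test_that("known confusion diagonals are recovered as category sensitivities", {
  cfg <- simulation_config(
    n_raters_per_group = c(`3` = 10L),
    n_images_per_category = c(AKIEC = 5L, BCC = 6L, BKL = 8L, DF = 5L,
                              MEL = 8L, NV = 9L, VASC = 4L),
    accuracy_sd = 0, difficulty_mean = 0, difficulty_spread = 0,
    confident_fraction = 0, timeout_rate = 0, incomplete_round_rate = 0,
    rounds_distribution = list(mean = 6, heavy_prob = 0, heavy_mean = 25),
    seed = 77L)
  co <- simulate_cohort(cfg)
  pia <- per_image_accuracy(drop_invalid(co$ratings), co$images)
  tab <- category_sensitivity_table(pia)
  p <- cfg$group_accuracy[["3"]]
  # every category's sensitivity near the configured diagonal
  expect_true(all(abs(tab$sensitivity - p) < 0.08))
})
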