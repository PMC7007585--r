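test_that("overlap join pairs only images present in both cells", {
  a <- tibble::tibble(image_id = c("1", "2", "3"), accuracy = c(1, 0.5, 0))
  b <- tibble::tibble(image_id = c("2", "3", "4"), accuracy = c(0.5, 1, 1))
  pairs <- overlap_join(a, b)
  expect_equal(sort(pairs$image_id), c("2", "3"))
  expect_equal(attr(pairs, "n_excluded"), 2L)
  full <- overlap_join(a, a)
  expect_equal(nrow(full), 3L)
  disjoint <- overlap_join(a, tibble::tibble(image_id = "9", accuracy = 1))
  expect_error(paired_t(disjoint), class = "crowddx_not_computable")
})

test_that("paired t agrees with the first-principles formula", {
  # frozen example: differences (1, 1, 2) in accuracy units
  pairs <- tibble::tibble(image_id = as.character(1:3),
                          accuracy_a = c(0, 0, 0), accuracy_b = c(1, 1, 2))
  out <- paired_t(pairs)
  expect_equal(out$mean_difference, 400 / 3, tolerance = 1e-10)
  expect_equal(out$t_statistic, 4, tolerance = 1e-10)
  expect_equal(out$p_raw, 2 * stats::pt(-4, df = 2), tolerance = 1e-10)
  # brute-force agreement on random fixtures
  set.seed(55)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    a <- runif(n)
    b <- runif(n)
    res <- paired_t(tibble::tibble(image_id = as.character(1:n),
                                   accuracy_a = a, accuracy_b = b))
    d <- b - a
    tstat <- mean(d) / (sd(d) / sqrt(n))
    pval <- 2 * stats::pt(-abs(tstat), df = n - 1)
    half <- stats::qt(0.975, n - 1) * sd(d) / sqrt(n)
    expect_equal(res$t_statistic, tstat, tolerance = 1e-10)
    expect_equal(res$p_raw, pval, tolerance = 1e-10)
    expect_equal(res$ci_lower, (mean(d) - half) * 100, tolerance = 1e-10)
    expect_true(res$ci_lower <= res$mean_difference &
                  res$mean_difference <= res$ci_upper)
  }
})

test_that("paired t is antisymmetric and degenerate cases are flagged", {
  pairs <- tibble::tibble(image_id = as.character(1:5),
                          accuracy_a = c(0.2, 0.4, 0.6, 0.8, 1),
                          accuracy_b = c(0.3, 0.3, 0.9, 0.7, 1))
  fwd <- paired_t(pairs)
  rev <- paired_t(dplyr::rename(pairs, accuracy_a = "accuracy_b",
                                accuracy_b = "accuracy_a"))
  expect_equal(rev$mean_difference, -fwd$mean_difference)
  expect_equal(rev$ci_lower, -fwd$ci_upper)
  expect_equal(rev$p_raw, fwd$p_raw)
  same <- tibble::tibble(image_id = as.character(1:4),
                         accuracy_a = c(0.1, 0.5, 0.9, 0.3),
                         accuracy_b = c(0.1, 0.5, 0.9, 0.3))
  expect_warning(res <- paired_t(same), "Zero variance")
  expect_equal(res$mean_difference, 0)
  expect_true(is.na(res$p_raw))
})

test_that("Holm adjustment follows the step-down rule", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.03), 0.03)
  # independent hand-rolled step-down oracle on random vectors
  holm_oracle <- function(p) {
    m <- length(p)
    ord <- order(p)
    adj <- pmin(1, (m - seq_len(m) + 1) * p[ord])
    adj <- cummax(adj)
    out <- numeric(m)
    out[ord] <- adj
    out
  }
  set.seed(66)
  for (i in 1:25) {
    p <- runif(sample(2:12, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, holm_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_equal(order(adj[order(p)]), seq_along(p))
  }
})

test_that("Holm controls the family-wise error rate under the global null", {
  set.seed(88)
  n_families <- 400
  m <- 5
  n <- 25
  fwer_hits <- 0L
  for (f in seq_len(n_families)) {
    p <- vapply(seq_len(m), function(j) {
      d <- rnorm(n) # both cells identical in distribution: null differences
      stats::t.test(d)$p.value
    }, numeric(1))
    if (any(holm_adjust(p) < 0.05)) fwer_hits <- fwer_hits + 1L
  }
  fwer <- fwer_hits / n_families
  # alpha plus 3 binomial SEs
  expect_lt(fwer, 0.05 + 3 * sqrt(0.05 * 0.95 / n_families))
})

test_that("comparison family labels cells and marks the reference", {
  cells <- list(
    `nonexpert|single|all` = tibble::tibble(image_id = as.character(1:6),
                                            accuracy = c(0.5, 0.4, 0.6,
                                                         0.5, 0.3, 0.7)),
    `nonexpert|4|all` = tibble::tibble(image_id = as.character(1:6),
                                       accuracy = c(0.7, 0.6, 0.9,
                                                    0.6, 0.4, 0.8)),
    `expert|single|all` = tibble::tibble(image_id = as.character(c(1:4, 9)),
                                         accuracy = c(0.9, 0.5, 0.7,
                                                      0.6, 1)))
  info <- tibble::tibble(label = names(cells),
                         group = c("nonexpert", "nonexpert", "expert"),
                         k = c(NA, 4L, NA),
                         confidence = "all")
  out <- compare_to_baseline(cells, info, baseline = "nonexpert|single|all")
  expect_equal(out$reference, c(TRUE, FALSE, FALSE))
  expect_equal(out$mean_difference[1], 0)
  expect_equal(out$n_images, c(6L, 6L, 4L))
  expect_true(all(out$p_adjusted >= out$p_raw, na.rm = TRUE))
  # collective cell improved on every image: positive difference
  expect_gt(out$mean_difference[2], 0)
})
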