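# In-code fixtures shared across tests. All randomness is seeded locally.

# A tiny deterministic ratings table built by hand (no simulation).
make_ratings <- function(rater_id, image_id, round_index, predicted,
                         answer_time_s = 3, valid = TRUE) {
  tibble::tibble(rater_id = rater_id, image_id = image_id,
                 round_index = round_index, predicted = predicted,
                 answer_time_s = answer_time_s, valid = valid)
}

# One rater playing `n_rounds` rounds of `n_per_round` distinct images,
# all valid, all correct on "MEL" images unless overridden.
make_rounds <- function(rater_id = "R1", n_rounds = 3, n_per_round = 30,
                        predicted = "MEL", answer_time_s = 3) {
  do.call(rbind, lapply(seq_len(n_rounds), function(r) {
    make_ratings(rater_id = rater_id,
                 image_id = sprintf("I%02d", seq_len(n_per_round)),
                 round_index = r, predicted = predicted,
                 answer_time_s = answer_time_s)
  }))
}

# A small image pool ample for the default blueprint.
make_pool <- function(n_per_cat = 12) {
  cats <- diagnosis_categories()
  truth <- rep(cats, each = n_per_cat)
  stratum <- rep("not_applicable", length(truth))
  is_nv <- truth == "NV"
  stratum[is_nv] <- rep(nv_strata(), length.out = sum(is_nv))
  tibble::tibble(image_id = sprintf("P%03d", seq_along(truth)),
                 truth = truth,
                 is_malignant = truth %in% malignant_categories(),
                 nv_stratum = stratum,
                 difficulty = 0,
                 distractor = ifelse(truth == "MEL", "NV", "MEL"))
}

# Small config for fast simulation tests.
small_sim_config <- function(seed = 42L, ...) {
  simulation_config(
    n_raters_per_group = c(`1` = 2L, `3` = 2L, `5` = 2L),
    n_images_per_category = c(AKIEC = 4L, BCC = 5L, BKL = 6L, DF = 4L,
                              MEL = 6L, NV = 9L, VASC = 3L),
    seed = seed, ...)
}
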