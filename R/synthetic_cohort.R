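# Synthetic reader-study cohort: raters, images, 30-image batches, ratings.
#
# The generator emulates the statistical structure a gamified reader study
# produces: raters of five experience groups (group 5 = experts) with
# heterogeneous 7x7 confusion matrices, per-image difficulty that correlates
# errors across raters, a latent per-answer "confident" state that makes
# answers both faster and more accurate, lognormal answer times capped by a
# 25-second timeout, variable round counts with a heavy tail, and rounds
# occasionally truncated before all 30 images are shown.
#
# Image difficulty d mixes a rater's confusion row with an image-specific
# error row (weight d) whose mass concentrates on the image's distractor
# category: hard images pull every rater toward the same wrong look-alike
# diagnosis, which is what caps collective voting gains on real reader data.

#' Batch blueprint
#'
#' The fixed disease composition of one 30-image round: 3 AKIEC, 4 BCC,
#' 4 BKL, 3 DF, 5 MEL, 9 NV and 2 VASC, with the 9 NV drawn 3 from each
#' ground-truth stratum (histopathology / follow-up / consensus).
#'
#' @param counts Named integer vector over all 7 categories.
#' @param nv_per_stratum NV cases drawn per stratum; `3 * nv_per_stratum`
#'   must equal `counts["NV"]`.
#' @return A `batch_blueprint` object.
#' @export
#' @examples
#' batch_blueprint()
batch_blueprint <- function(counts = c(AKIEC = 3L, BCC = 4L, BKL = 4L,
                                       DF = 3L, MEL = 5L, NV = 9L, VASC = 2L),
                            nv_per_stratum = counts[["NV"]] %/% 3L) {
  if (!setequal(names(counts), DX_CATEGORIES)) {
    abort("`counts` must be named with exactly the 7 diagnosis categories.")
  }
  counts <- as.integer(counts[DX_CATEGORIES])
  names(counts) <- DX_CATEGORIES
  if (any(counts < 0)) abort("Blueprint counts must be nonnegative.")
  if (3L * nv_per_stratum != counts[["NV"]]) {
    abort("`nv_per_stratum` * 3 must equal counts[\"NV\"].")
  }
  structure(list(counts = counts, nv_per_stratum = as.integer(nv_per_stratum)),
            class = "batch_blueprint")
}

#' Simulation configuration
#'
#' Parameters of the synthetic cohort. Defaults are a desk-scale rendering of
#' a large web-based reader study: ~50 raters across the five experience
#' groups, 211 images with category frequencies proportional to the study
#' pool, roughly 25 ratings per image, mean answer times near 5 s, and a
#' small rate of timeouts and truncated rounds.
#'
#' @param n_raters_per_group Named integer vector, names among "1".."5"
#'   (group 5 = experts).
#' @param n_images_per_category Named integer vector over the 7 categories;
#'   the NV count must be divisible by 3 (stratification).
#' @param group_accuracy Mean confusion-matrix diagonal per experience group.
#' @param accuracy_sd Between-rater SD of the diagonal (0 = identical raters).
#' @param group_log_time Mean of log answer time (log seconds) per group.
#' @param time_log_sd Within-rater SD of log answer time.
#' @param time_jitter_sd Between-rater SD of the log-time location.
#' @param confident_fraction Probability an answer is given in the latent
#'   confident state.
#' @param confident_speed_factor Multiplier (< 1) on answer time when
#'   confident.
#' @param confident_accuracy_boost Factor (>= 1) by which the off-diagonal
#'   confusion mass is shrunk when confident.
#' @param rounds_distribution List with `mean` (geometric-like mean round
#'   count), `heavy_prob` and `heavy_mean` (a small heavy-tailed component so
#'   a few raters exceed the 30-round analysis cap).
#' @param timeout_rate Probability an answer times out (recorded invalid,
#'   25 s, no prediction).
#' @param incomplete_round_rate Probability a round is abandoned before all
#'   30 images are answered.
#' @param difficulty_mean,difficulty_spread Mean and SD of per-image
#'   difficulty in \[0,1\]; difficulty `d` mixes a rater's confusion row with
#'   the image's error row with weight `d`.
#' @param distractor_share Fraction of the difficulty error row placed on
#'   the image's distractor category (the remainder is uniform over the
#'   other wrong categories). 0 recovers a purely uniform error row; values
#'   near 1 make hard images hard in the same way for every rater, which
#'   realistically limits what plurality voting can recover.
#' @param timeout_s Per-image time limit in seconds.
#' @param seed Master seed (mandatory for reproducibility).
#' @return A validated `simulation_config` object.
#' @export
simulation_config <- function(n_raters_per_group = c(`1` = 11L, `2` = 11L,
                                                     `3` = 11L, `4` = 11L,
                                                     `5` = 6L),
                              n_images_per_category = c(AKIEC = 16L, BCC = 26L,
                                                        BKL = 55L, DF = 6L,
                                                        MEL = 56L, NV = 45L,
                                                        VASC = 7L),
                              group_accuracy = c(`1` = 0.58, `2` = 0.63,
                                                 `3` = 0.68, `4` = 0.73,
                                                 `5` = 0.78),
                              accuracy_sd = 0.06,
                              group_log_time = c(`1` = log(5.6), `2` = log(5.4),
                                                 `3` = log(5.2), `4` = log(5.0),
                                                 `5` = log(4.4)),
                              time_log_sd = 0.6,
                              time_jitter_sd = 0.2,
                              confident_fraction = 0.5,
                              confident_speed_factor = 0.45,
                              confident_accuracy_boost = 1.25,
                              rounds_distribution = list(mean = 3.5,
                                                         heavy_prob = 0.02,
                                                         heavy_mean = 25),
                              timeout_rate = 0.02,
                              incomplete_round_rate = 0.05,
                              difficulty_mean = 0.15,
                              difficulty_spread = 0.2,
                              distractor_share = 0.8,
                              timeout_s = 25,
                              seed = 1L) {
  cfg <- list(n_raters_per_group = n_raters_per_group,
              n_images_per_category = n_images_per_category,
              group_accuracy = group_accuracy,
              accuracy_sd = accuracy_sd,
              group_log_time = group_log_time,
              time_log_sd = time_log_sd,
              time_jitter_sd = time_jitter_sd,
              confident_fraction = confident_fraction,
              confident_speed_factor = confident_speed_factor,
              confident_accuracy_boost = confident_accuracy_boost,
              rounds_distribution = rounds_distribution,
              timeout_rate = timeout_rate,
              incomplete_round_rate = incomplete_round_rate,
              difficulty_mean = difficulty_mean,
              difficulty_spread = difficulty_spread,
              distractor_share = distractor_share,
              timeout_s = timeout_s,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  problems <- character()
  add <- function(msg) problems <<- c(problems, msg)
  if (!all(names(cfg$n_raters_per_group) %in% as.character(1:5))) {
    add("n_raters_per_group: names must be experience groups \"1\"..\"5\"")
  }
  if (any(cfg$n_raters_per_group < 0)) add("n_raters_per_group: counts must be >= 0")
  if (!setequal(names(cfg$n_images_per_category), DX_CATEGORIES)) {
    add("n_images_per_category: must name exactly the 7 categories")
  } else if (cfg$n_images_per_category[["NV"]] %% 3L != 0L) {
    add("n_images_per_category: NV count must be divisible by 3 (strata)")
  }
  for (p in c("confident_fraction", "timeout_rate", "incomplete_round_rate")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) add(paste0(p, ": must lie in [0,1]"))
  }
  if (cfg$confident_speed_factor <= 0 || cfg$confident_speed_factor >= 1) {
    add("confident_speed_factor: must lie in (0,1)")
  }
  if (cfg$confident_accuracy_boost < 1) add("confident_accuracy_boost: must be >= 1")
  if (cfg$difficulty_mean < 0 || cfg$difficulty_mean > 1) add("difficulty_mean: must lie in [0,1]")
  if (cfg$difficulty_spread < 0) add("difficulty_spread: must be >= 0")
  if (cfg$distractor_share < 0 || cfg$distractor_share > 1) add("distractor_share: must lie in [0,1]")
  if (any(cfg$group_accuracy <= 0 | cfg$group_accuracy >= 1)) {
    add("group_accuracy: diagonals must lie in (0,1)")
  }
  if (is.null(cfg$seed) || is.na(cfg$seed)) add("seed: mandatory")
  if (length(problems)) {
    abort(c("Invalid simulation configuration:", problems))
  }
  invisible(cfg)
}

# Plausible inter-category confusability weights (symmetric, zero diagonal):
# melanocytic lesions (MEL/NV) and keratinocytic lesions (AKIEC/BKL/BCC) are
# mutually harder to tell apart than unrelated pairs.
category_similarity <- function() {
  m <- matrix(1, 7, 7, dimnames = list(DX_CATEGORIES, DX_CATEGORIES))
  boost <- function(a, b, w) {
    m[a, b] <<- w
    m[b, a] <<- w
  }
  boost("MEL", "NV", 4)
  boost("MEL", "BKL", 2)
  boost("AKIEC", "BKL", 3)
  boost("AKIEC", "BCC", 2)
  boost("BCC", "BKL", 1.5)
  boost("DF", "NV", 1.5)
  diag(m) <- 0
  m
}

# Row-stochastic 7x7 confusion matrix with the given diagonal, off-diagonal
# mass split by confusability weights.
build_confusion <- function(accuracy, similarity = category_similarity()) {
  stopifnot(accuracy > 0, accuracy < 1)
  m <- matrix(0, 7, 7, dimnames = list(DX_CATEGORIES, DX_CATEGORIES))
  for (i in seq_len(7)) {
    w <- similarity[i, ]
    m[i, ] <- (1 - accuracy) * w / sum(w)
    m[i, i] <- accuracy
  }
  m
}

# Shrink a confusion row's off-diagonal mass by `boost` (>= 1), keeping it
# row-stochastic: the confident-state sharpening.
sharpen_row <- function(row, truth, boost) {
  out <- row / boost
  out[truth] <- 1 - (1 - row[truth]) / boost
  out
}

draw_n_rounds <- function(rd) {
  if (runif(1) < rd$heavy_prob) {
    20L + rgeom(1, 1 / rd$heavy_mean)
  } else {
    1L + rgeom(1, 1 / rd$mean)
  }
}

#' Generate synthetic rater profiles
#'
#' One profile per requested rater: an experience group, a row-stochastic
#' confusion matrix whose diagonal is drawn around the group mean, a
#' lognormal timing model, the confident-state parameters, a round count,
#' and registration/activity days (used by [unbounded_retention()]).
#' Group 5 raters are experts and have stochastically higher diagonal mass
#' than groups 1–4 under the default parameters.
#'
#' @param config A [simulation_config()]. Deterministic given `config$seed`.
#' @return Tibble with one row per rater; `confusion` and `activity_days`
#'   are list-columns.
#' @export
generate_raters <- function(config = simulation_config()) {
  validate_simulation_config(config)
  set.seed(config$seed)
  ng <- config$n_raters_per_group
  groups <- rep(as.integer(names(ng)), times = ng)
  n <- length(groups)
  if (n == 0L) abort("Configuration requests zero raters.")
  sim <- category_similarity()
  out <- vector("list", n)
  for (i in seq_len(n)) {
    g <- groups[i]
    gkey <- as.character(g)
    if (!gkey %in% names(config$group_accuracy)) {
      abort(paste0("No group_accuracy entry for experience group ", gkey))
    }
    acc <- min(0.98, max(0.15, rnorm(1, config$group_accuracy[[gkey]],
                                     config$accuracy_sd)))
    n_rounds <- draw_n_rounds(config$rounds_distribution)
    # return visits: Poisson count of revisits with geometric gaps, giving a
    # 30-day unbounded retention near 30% within the 100-day window
    n_return <- rpois(1, 1.5)
    activity <- 0L
    if (n_rounds > 0L && n_return > 0L) {
      gaps <- 1L + rgeom(n_return, 1 / 18)
      days <- cumsum(gaps)
      activity <- c(0L, as.integer(days[days <= 100]))
    }
    out[[i]] <- tibble::tibble(
      rater_id = sprintf("R%03d", i),
      experience_group = g,
      is_expert = g == 5L,
      accuracy = acc,
      confusion = list(build_confusion(acc, sim)),
      time_log_mean = rnorm(1, config$group_log_time[[gkey]],
                            config$time_jitter_sd),
      time_log_sd = config$time_log_sd,
      confident_fraction = config$confident_fraction,
      confident_speed_factor = config$confident_speed_factor,
      confident_accuracy_boost = config$confident_accuracy_boost,
      n_rounds = n_rounds,
      registration_day = sample(0:364, 1),
      activity_days = list(unique(activity))
    )
  }
  dplyr::bind_rows(out)
}

#' Generate a synthetic image pool
#'
#' One record per image: ground-truth category, malignancy flag, NV stratum
#' (evenly assigned; `not_applicable` outside NV), a difficulty in \[0,1\]
#' drawn from a Beta distribution matched to
#' `difficulty_mean`/`difficulty_spread`, and a distractor category (a wrong
#' look-alike, drawn with confusability weights). Difficulty `d` pulls every
#' rater's confusion row toward the image's error row with weight `d`, so
#' hard images are hard for everyone and mostly in the same way — the
#' inter-rater correlation that limits collective gains.
#'
#' @param config A [simulation_config()]. Deterministic given `config$seed`.
#' @return Tibble: `image_id`, `truth`, `is_malignant`, `nv_stratum`,
#'   `difficulty`.
#' @export
generate_images <- function(config = simulation_config()) {
  validate_simulation_config(config)
  set.seed(config$seed + 1L)
  counts <- config$n_images_per_category[DX_CATEGORIES]
  truth <- rep(DX_CATEGORIES, times = counts)
  n <- length(truth)
  m <- config$difficulty_mean
  s <- config$difficulty_spread
  if (m <= 0) {
    difficulty <- rep(0, n)
  } else if (s == 0) {
    difficulty <- rep(m, n)
  } else {
    v <- min(s^2, 0.95 * m * (1 - m))
    a <- m * (m * (1 - m) / v - 1)
    b <- (1 - m) * (m * (1 - m) / v - 1)
    difficulty <- rbeta(n, a, b)
  }
  stratum <- rep("not_applicable", n)
  is_nv <- truth == "NV"
  stratum[is_nv] <- rep(NV_STRATA, length.out = sum(is_nv))
  sim <- category_similarity()
  distractor <- vapply(truth, function(tr) {
    w <- sim[tr, ]
    sample(DX_CATEGORIES, 1L, prob = w)
  }, character(1), USE.NAMES = FALSE)
  tibble::tibble(
    image_id = sprintf("I%04d", seq_len(n)),
    truth = truth,
    is_malignant = truth %in% DX_MALIGNANT,
    nv_stratum = stratum,
    difficulty = difficulty,
    distractor = distractor
  )
}

#' Sample one 30-image batch
#'
#' Draws a round's images at random from the pool according to the blueprint
#' composition, with NV stratified evenly over the three ground-truth
#' strata and no duplicate image within the batch. Uses the current RNG
#' state (seed upstream for reproducibility).
#'
#' @param pool Image tibble as from [generate_images()].
#' @param blueprint A [batch_blueprint()].
#' @return Tibble of `sum(blueprint$counts)` image rows in presentation
#'   order.
#' @export
sample_batch <- function(pool, blueprint = batch_blueprint()) {
  picks <- vector("list", 0L)
  for (cat in DX_CATEGORIES) {
    need <- blueprint$counts[[cat]]
    if (need == 0L) next
    if (cat == "NV") {
      for (st in NV_STRATA) {
        sub <- pool[pool$truth == "NV" & pool$nv_stratum == st, , drop = FALSE]
        if (nrow(sub) < blueprint$nv_per_stratum) {
          abort(sprintf("Image pool exhausted for category NV (stratum %s): need %d, have %d",
                        st, blueprint$nv_per_stratum, nrow(sub)),
                class = "crowddx_pool_exhausted")
        }
        picks[[length(picks) + 1L]] <-
          sub[sample.int(nrow(sub), blueprint$nv_per_stratum), , drop = FALSE]
      }
    } else {
      sub <- pool[pool$truth == cat, , drop = FALSE]
      if (nrow(sub) < need) {
        abort(sprintf("Image pool exhausted for category %s: need %d, have %d",
                      cat, need, nrow(sub)),
              class = "crowddx_pool_exhausted")
      }
      picks[[length(picks) + 1L]] <- sub[sample.int(nrow(sub), need), , drop = FALSE]
    }
  }
  batch <- dplyr::bind_rows(picks)
  batch[sample.int(nrow(batch)), , drop = FALSE]
}

#' Simulate ratings
#'
#' Plays every rater through `n_rounds` batches. Per answer: a latent
#' confident state is drawn with probability `confident_fraction`; the
#' answer time is lognormal, multiplied by `confident_speed_factor` when
#' confident and clipped to `(0, timeout_s]`; with probability
#' `timeout_rate` the answer is invalid (no prediction, time = timeout);
#' otherwise the predicted category is drawn from the truth row of the
#' rater's confusion matrix, sharpened toward the diagonal when confident
#' and flattened toward uniform error by the image's difficulty. Rounds are
#' truncated below 30 answers with probability `incomplete_round_rate`.
#'
#' @param raters Tibble from [generate_raters()].
#' @param pool Image tibble from [generate_images()].
#' @param blueprint A [batch_blueprint()].
#' @param config A [simulation_config()]. Deterministic given `config$seed`.
#' @return Long ratings tibble: `rater_id`, `image_id`, `round_index`,
#'   `predicted` (NA when invalid), `answer_time_s`, `valid`.
#' @export
simulate_ratings <- function(raters, pool, blueprint = batch_blueprint(),
                             config = simulation_config()) {
  validate_simulation_config(config)
  if (nrow(raters) == 0L || nrow(pool) == 0L) {
    abort("`raters` and `pool` must be nonempty.")
  }
  set.seed(config$seed + 2L)
  timeout_s <- config$timeout_s
  out <- vector("list", 0L)
  for (i in seq_len(nrow(raters))) {
    cm <- raters$confusion[[i]]
    tlm <- raters$time_log_mean[i]
    tls <- raters$time_log_sd[i]
    cf <- raters$confident_fraction[i]
    csf <- raters$confident_speed_factor[i]
    boost <- raters$confident_accuracy_boost[i]
    for (r in seq_len(raters$n_rounds[i])) {
      batch <- sample_batch(pool, blueprint)
      n_show <- nrow(batch)
      if (n_show > 1L && runif(1) < config$incomplete_round_rate) {
        n_show <- sample.int(nrow(batch) - 1L, 1L)
        batch <- batch[seq_len(n_show), , drop = FALSE]
      }
      confident <- runif(n_show) < cf
      t <- exp(rnorm(n_show, tlm, tls)) * ifelse(confident, csf, 1)
      t <- pmin(t, timeout_s)
      timed_out <- runif(n_show) < config$timeout_rate
      predicted <- rep(NA_character_, n_show)
      for (j in seq_len(n_show)) {
        if (timed_out[j]) next
        tr <- batch$truth[j]
        row <- cm[tr, ]
        if (confident[j]) row <- sharpen_row(row, tr, boost)
        d <- batch$difficulty[j]
        if (d > 0) {
          share <- config$distractor_share
          err <- rep((1 - share) / 5, 7)
          names(err) <- DX_CATEGORIES
          err[tr] <- 0
          err[batch$distractor[j]] <- share
          row <- (1 - d) * row + d * err
        }
        predicted[j] <- sample(DX_CATEGORIES, 1L, prob = row)
      }
      t[timed_out] <- timeout_s
      out[[length(out) + 1L]] <- tibble::tibble(
        rater_id = raters$rater_id[i],
        image_id = batch$image_id,
        round_index = r,
        predicted = predicted,
        answer_time_s = t,
        valid = !timed_out
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Simulate a full cohort
#'
#' Convenience wrapper: raters, images and ratings in one deterministic call
#' (the rater, image and rating streams use `seed`, `seed + 1`, `seed + 2`).
#'
#' @param config A [simulation_config()].
#' @param blueprint A [batch_blueprint()].
#' @return List with tibbles `raters`, `images`, `ratings` and the `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(simulation_config(
#'   n_raters_per_group = c(`1` = 2L, `5` = 1L),
#'   n_images_per_category = c(AKIEC = 3L, BCC = 4L, BKL = 4L, DF = 3L,
#'                             MEL = 5L, NV = 9L, VASC = 2L),
#'   seed = 7L))
#' nrow(cohort$ratings)
simulate_cohort <- function(config = simulation_config(),
                            blueprint = batch_blueprint()) {
  raters <- generate_raters(config)
  images <- generate_images(config)
  ratings <- simulate_ratings(raters, images, blueprint, config)
  list(raters = raters, images = images, ratings = ratings, config = config)
}
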