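# Virtual collectives: bootstrap plurality voting over an image's pool of
# answers, with random tie-breaking, plus an exact enumeration oracle.

#' Collective voting configuration
#'
#' @param sizes Collective sizes to evaluate (default 3:8; size 1 is the
#'   degenerate single-rater baseline and is allowed).
#' @param n_replicates Bootstrap replicates per (image, size) cell.
#' @param seed Master seed; it spawns one independent substream per
#'   (image, size) cell so excluding an image does not shift other cells'
#'   draws.
#' @param tie_rule Only `"uniform_random"` is defined: plurality ties are
#'   broken uniformly at random per replicate.
#' @param method `"bootstrap"` (default) or `"exact"` (full multinomial
#'   enumeration, exact expected accuracy; no Monte Carlo error).
#' @return A `collective_config` object.
#' @export
collective_config <- function(sizes = 3:8, n_replicates = 1000L, seed = 1L,
                              tie_rule = "uniform_random",
                              method = c("bootstrap", "exact")) {
  if (any(sizes < 1L)) abort("Collective sizes must be >= 1.")
  if (n_replicates < 1L) abort("n_replicates must be >= 1.")
  tie_rule <- match.arg(tie_rule, "uniform_random")
  structure(list(sizes = as.integer(sort(unique(sizes))),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 tie_rule = tie_rule,
                 method = match.arg(method)),
            class = "collective_config")
}

#' First-past-the-post vote with random tie-breaking
#'
#' The category with the most votes wins; if several categories tie at the
#' maximum, one of them is drawn uniformly at random from the current RNG
#' state.
#'
#' @param votes Nonempty character vector of category codes.
#' @return A single category code.
#' @export
#' @examples
#' majority_vote(c("MEL", "MEL", "NV"))
majority_vote <- function(votes) {
  if (length(votes) == 0L) abort("Cannot take a vote over zero answers.")
  assert_categories(votes)
  tab <- table(votes)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1L) winners else winners[sample.int(length(winners), 1L)]
}

# Content-addressed RNG substream per (image, size) cell: a multiplicative
# fold of "<master seed>|<image id>|<k>" into a positive 31-bit integer, so
# an image's draws depend only on the master seed and its own identity,
# never on which other images are present. (All intermediates stay below
# 2^53, so the arithmetic is exact in doubles.)
cell_seed <- function(master_seed, image_id, k) {
  bytes <- utf8ToInt(paste(master_seed, image_id, k, sep = "|"))
  h <- 104729
  for (b in bytes) {
    h <- (h * 69069 + b) %% 2147483648
  }
  as.integer(h %% 2147483647) + 1L
}

# All compositions of k into m nonnegative parts, as a matrix (rows =
# compositions). choose(k + m - 1, m - 1) rows; fine for k <= 12, m <= 7.
compositions <- function(k, m) {
  if (m == 1L) return(matrix(k, 1L, 1L))
  out <- vector("list", k + 1L)
  for (i in 0:k) {
    rest <- compositions(k - i, m - 1L)
    out[[i + 1L]] <- cbind(i, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' Exact win probabilities of a virtual collective
#'
#' Enumerates every multinomial outcome of drawing `k` answers with
#' replacement from the empirical answer distribution and accumulates, for
#' each category, the probability that it wins the plurality vote (ties
#' contribute `1/#tied`).
#'
#' @param answers Character vector: the image's pool of answers.
#' @param k Collective size (enumeration is exponential-ish in `k`; capped
#'   at 12).
#' @return Named numeric vector over all 7 categories, summing to 1.
#' @export
collective_vote_distribution <- function(answers, k) {
  if (length(answers) == 0L) abort("Empty answer pool.")
  if (k < 1L) abort("Collective size must be >= 1.")
  if (k > 12L) abort("Exact enumeration supported only for k <= 12.")
  assert_categories(answers)
  tab <- table(answers)
  cats <- names(tab)
  p <- as.numeric(tab) / sum(tab)
  m <- length(cats)
  cm <- compositions(as.integer(k), m)
  logp <- lgamma(k + 1) - rowSums(lgamma(cm + 1)) +
    as.vector(cm %*% log(p))
  prob <- exp(logp)
  mx <- apply(cm, 1L, max)
  iswin <- cm == mx
  nwin <- rowSums(iswin)
  res <- setNames(numeric(7), DX_CATEGORIES)
  for (j in seq_len(m)) {
    res[cats[j]] <- sum(prob * iswin[, j] / nwin)
  }
  res
}

#' Exact collective accuracy
#'
#' Probability that a bootstrap collective of size `k` drawn from the
#' image's answers votes for the true category — the analytic limit of
#' [bootstrap_collective()] as the number of replicates grows.
#'
#' @param answers Character vector of answers.
#' @param truth True category of the image.
#' @param k Collective size.
#' @return Probability in \[0, 1\].
#' @export
#' @examples
#' # 3 of 5 answers correct, panels of 3:
#' exact_collective_accuracy(c("MEL", "MEL", "MEL", "NV", "NV"), "MEL", 3)
exact_collective_accuracy <- function(answers, truth, k) {
  assert_categories(truth)
  unname(collective_vote_distribution(answers, k)[truth])
}

# Vectorised replicate voting: draws a B x k matrix of answers (indices into
# the 7 categories), tallies, and picks per-row winners with uniform random
# tie-breaking (max.col ties.method = "random").
replicate_votes <- function(answers, k, n_replicates) {
  idx <- match(answers, DX_CATEGORIES)
  draws <- matrix(sample(idx, n_replicates * k, replace = TRUE),
                  nrow = n_replicates)
  counts <- vapply(seq_len(7),
                   function(cat) rowSums(draws == cat),
                   numeric(n_replicates))
  if (n_replicates == 1L) counts <- matrix(counts, nrow = 1L)
  DX_CATEGORIES[max.col(counts, ties.method = "random")]
}

#' Bootstrap collective accuracy for one image
#'
#' Draws `n_replicates` virtual collectives of `k` answers with replacement
#' from the image's answer pool, takes the plurality vote of each (ties
#' broken uniformly at random), and reports the fraction of replicates
#' voting the true category, plus the fraction voting any malignant
#' category. Deterministic given the current RNG state.
#'
#' @param answers Character vector of answers; must contain at least `k`
#'   elements (images with fewer raters than the collective size are
#'   excluded upstream).
#' @param truth True category.
#' @param k Collective size.
#' @param n_replicates Number of bootstrap replicates.
#' @return Tibble row: `accuracy`, `p_malignant`, `n_answers`,
#'   `n_replicates`, `method`.
#' @export
bootstrap_collective <- function(answers, truth, k, n_replicates = 1000L) {
  if (k < 1L) abort("Collective size must be >= 1.")
  if (length(answers) < k) {
    abort(sprintf("Image has %d answers, fewer than collective size %d; excluded.",
                  length(answers), k),
          class = "crowddx_too_few_answers")
  }
  assert_categories(c(answers, truth))
  votes <- replicate_votes(answers, k, n_replicates)
  tibble::tibble(accuracy = mean(votes == truth),
                 p_malignant = mean(votes %in% DX_MALIGNANT),
                 n_answers = length(answers),
                 n_replicates = as.integer(n_replicates),
                 method = "bootstrap")
}

exact_collective <- function(answers, truth, k) {
  dist <- collective_vote_distribution(answers, k)
  tibble::tibble(accuracy = unname(dist[truth]),
                 p_malignant = sum(dist[DX_MALIGNANT]),
                 n_answers = length(answers),
                 n_replicates = NA_integer_,
                 method = "exact")
}

#' Build per-image answer sets
#'
#' Collapses a cleaned ratings table (one cell: a group and confidence
#' stratum) to one row per image with the multiset of answers.
#'
#' @param ratings Cleaned, valid ratings.
#' @param images Image tibble (for the `truth` join), or NULL if `ratings`
#'   already carries `truth`.
#' @return Tibble: `image_id`, `truth`, `answers` (list-column),
#'   `n_answers`.
#' @export
image_answer_sets <- function(ratings, images = NULL) {
  if (!"truth" %in% names(ratings)) {
    if (is.null(images)) abort("Provide `images` or a `truth` column.")
    ratings <- dplyr::inner_join(ratings, images[, c("image_id", "truth")],
                                 by = "image_id")
  }
  ratings |>
    dplyr::group_by(.data$image_id, .data$truth) |>
    dplyr::summarise(answers = list(.data$predicted),
                     n_answers = dplyr::n(), .groups = "drop")
}

#' Run collectives over all images and sizes
#'
#' For every requested collective size `k`, every image whose answer pool
#' has at least `k` answers contributes one accuracy row; smaller pools are
#' excluded (and reported via `inform()`). Each (image, size) cell uses an
#' independent RNG substream spawned from the master seed.
#'
#' @param answer_sets Tibble from [image_answer_sets()].
#' @param config A [collective_config()].
#' @param verbose Report exclusions (default TRUE).
#' @return Tibble: `image_id`, `truth`, `k`, `accuracy`, `p_malignant`,
#'   `n_answers`, `n_replicates`, `method`.
#' @export
run_collectives <- function(answer_sets, config = collective_config(),
                            verbose = TRUE) {
  n_img <- nrow(answer_sets)
  sizes <- config$sizes
  rows <- vector("list", 0L)
  n_excluded <- 0L
  for (j in seq_along(sizes)) {
    k <- sizes[j]
    for (i in seq_len(n_img)) {
      answers <- answer_sets$answers[[i]]
      if (length(answers) < k) {
        n_excluded <- n_excluded + 1L
        next
      }
      res <- if (config$method == "exact") {
        exact_collective(answers, answer_sets$truth[i], k)
      } else {
        set.seed(cell_seed(config$seed, answer_sets$image_id[i], k))
        bootstrap_collective(answers, answer_sets$truth[i], k,
                             config$n_replicates)
      }
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(image_id = answer_sets$image_id[i],
                       truth = answer_sets$truth[i],
                       k = k),
        res)
    }
  }
  if (verbose && n_excluded > 0L) {
    inform(sprintf(
      "Excluded %d (image, size) cells with fewer answers than the collective size.",
      n_excluded))
  }
  dplyr::bind_rows(rows)
}
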