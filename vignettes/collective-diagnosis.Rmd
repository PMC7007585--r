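---
title: "Collective intelligence for skin lesion diagnosis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective intelligence for skin lesion diagnosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowddx)
```

## The problem

Diagnosing pigmented skin lesions from dermatoscopic images is a seven-class
problem — actinic keratosis/intraepithelial carcinoma (AKIEC), basal cell
carcinoma (BCC), benign keratinocytic lesions (BKL), dermatofibroma (DF),
melanoma (MEL), nevus (NV) and vascular lesions (VASC) — in which individual
readers, especially non-experts, make frequent errors. A *virtual collective*
asks several readers independently and takes the category with the most
votes (first-past-the-post; ties broken at random) as the collective
diagnosis. `crowddx` implements the full analysis pipeline for such reader
studies: cohort simulation, data cleaning, bootstrap collectives, diagnostic
metrics, and paired statistical comparison.

The package addresses a practical obstacle: raw reader-study ratings are
rarely deposited. Every stage is therefore developed and tested against a
synthetic cohort generator whose outputs have the statistical structure the
analysis assumes. The generator is first-class, tested code, not a fixture.

## The analysis pipeline

Ratings are long-format rows `(rater, image, round, predicted category,
answer time, valid flag)`. The cleaning filters run in a fixed order:

1. **drop_invalid** — answers that hit the 25-second timeout carry no
   diagnosis and are removed.
2. **cap_rounds** — each rater contributes at most their first 30 rounds, so
   heavy players cannot dominate pooled estimates.
3. **drop_incomplete_rounds** — a round is kept only if at least
   `min_answered_per_round` of its images were validly answered. The default
   is 16 (the literal "more than 50%" of 30); 15 is one flag away, because
   study descriptions are ambiguous between the two readings.
4. **select_rateable_images** — images with fewer than 8 ratings are
   excluded.

**Confidence.** Answer time is used as a surrogate for confidence: an answer
is *high confidence* iff its time is less than or equal to the rater's own
mean answer time (computed from that rater's valid answers, after
cleaning). The mean can alternatively be computed per rater *and* true
category (`confidence_policy("per_rater_category")`); the per-rater overall
mean is the default. High and low partition each rater's valid answers.

**Collectives.** For an image with answer pool $A$ and collective size $k
\in \{3,\dots,8\}$, a bootstrap replicate draws $k$ answers from $A$ with
replacement and takes the plurality vote, breaking ties uniformly at
random. The per-image collective accuracy is the fraction of $B$ replicates
voting the true category; images with $|A| < k$ are excluded for that $k$,
within the group/confidence cell being analysed. The resampling unit is the
answer, so one rater can appear twice in a virtual panel — the literal
bootstrap reading. $B$ defaults to 1000, giving a per-image Monte Carlo
standard error of at most $0.5/\sqrt{1000} \approx 0.016$, which averages
out over the hundreds of images entering any cell mean. An exact oracle
(`exact_collective_accuracy()`) enumerates all multinomial outcomes of the
$k$ draws — at most $\binom{k+6}{6}$ compositions — and scores ties as
$1/\#\text{tied}$; it both verifies the bootstrap in tests and provides
noise-free values for small panels. Tie-breaking happens inside each
replicate, the only reading under which every replicate casts exactly one
vote.

Every (image, size) cell draws from an RNG substream seeded by a hash of
(master seed, image id, size), so excluding an image — or analysing a
subset — never shifts any other image's draws.

**Metrics.** *Specific accuracy* scores the exact 7-class label; the cell
summary is the unweighted arithmetic mean of per-image accuracies (images
weigh equally regardless of how often they were rated). *Per-category
sensitivity* is the same mean restricted to images of one true category.
*Malignancy detection* collapses classes to malignant = {AKIEC, BCC, MEL}:
predicting any malignant category counts as detecting malignancy on any
malignant image. Sensitivity, specificity, PPV and NPV follow the standard
formulas with binomial confidence intervals — Wilson score by default
(well-behaved at the observed proportions and for fractional counts), with
Clopper–Pearson and the normal approximation selectable. Single-rater cells
pool answers (one classification per answer). For collective cells the
pooling unit of bootstrapped votes is genuinely ambiguous; `crowddx` uses
each image's *expected* vote — its malignant-vote probability across
replicates contributes fractionally to tp/fp/tn/fn, so `n` equals the
number of images. This is conservative (wider intervals than pooling all
replicates, which would overstate the evidence).

**Inference.** Cells are compared against the single-nonexpert baseline by
a two-sided paired *t* test on per-image accuracy differences over the
images present in both cells. Pairing per-image *fractions* correct is the
only scale-free pairing when cells have different answer counts per image;
differences are reported in percentage points with $t$-based 95% CIs.
The default family mirrors the customary report layout: single nonexperts
(low/high confidence), nonexpert collectives of 4 and 8 (all/low/high), and
single experts (all/low/high), all versus the baseline. P values are
Holm-adjusted over whatever family a report run emits; zero-variance
comparisons report their mean difference with an undefined p value rather
than failing the run.

## The synthetic cohort generator

The generator emulates, at desk scale, a gamified web reader study:

- **Raters.** Five experience groups (group 5 = experts). Each rater gets a
  row-stochastic 7×7 confusion matrix whose diagonal is drawn around the
  group mean (defaults 0.58/0.63/0.68/0.73/0.78, SD 0.06) with off-diagonal
  mass split by fixed confusability weights (MEL↔NV and the keratinocytic
  lesions are mutually harder). The group means were chosen so that the
  observed single-rater accuracies, after the difficulty and confidence
  mechanisms below, land near the high-50s% (nonexperts) and high-60s%
  (experts) typical of this reading task.
- **Batches.** Every round presents 30 images with the fixed composition
  3 AKIEC, 4 BCC, 4 BKL, 3 DF, 5 MEL, 9 NV (3 per ground-truth stratum:
  histopathology, follow-up, consensus) and 2 VASC, drawn at random without
  within-batch duplicates.
- **Speed–accuracy coupling.** A latent per-answer Bernoulli "confident"
  state (probability 0.5) multiplies the lognormal answer time by 0.45 and
  shrinks the confusion row's off-diagonal mass by the boost factor 1.25.
  Only the empirical association (faster answers are more accurate) is a
  study observation; the latent-state mechanism is the minimal model that
  reproduces it together with the high/low confidence ordering. Times are
  clipped to (0, 25] seconds; defaults give mean answer times near 5 s.
- **Image difficulty and the distractor.** Each image has a difficulty
  $d \in [0,1]$ (Beta, mean 0.15, SD 0.2) and a *distractor* category drawn
  by confusability. With weight $d$, every rater's answer row is mixed with
  an error row placing `distractor_share` (default 0.8) on the distractor
  and the rest uniformly on the other wrong categories. A purely uniform
  error row was tried first and rejected: it makes wrong votes spread over
  six categories, so plurality voting recovers the truth on essentially
  every image and collective accuracy runs away toward 100%. Concentrating
  hard images on a shared look-alike is what actually caps collective
  gains on real reader data; `distractor_share = 0` restores the uniform
  model.
- **Engagement.** Round counts are geometric-like (mean 3.5) with a small
  heavy-tailed component (2% of raters centred on ~44 rounds) so the
  30-round cap is genuinely exercised; rounds are truncated early with
  probability 0.05; answers time out (invalid, 25 s, no prediction) with
  probability 0.02. Revisit days follow a Poisson(1.5) count of returns
  with geometric gaps (mean 18 days), placing 30-day unbounded retention
  near 30% of raters within the 100-day window.

Defaults produce ≈50 raters (44 nonexperts, 6 experts), 211 images with
category frequencies proportional to a large dermatoscopic study pool, and
≈25 ratings per image — small enough that the full pipeline runs in seconds,
dense enough that collectives up to size 8 are estimable for most images.

What the generator does **not** emulate: real confusion structure beyond
the one-distractor approximation (real images can split raters over several
plausible wrong diagnoses, and rater errors correlate with training
background, not just the image); learning or fatigue over rounds;
screening-level gameplay; and device or recruitment effects. Consequently,
passing tests show the *pipeline* is correct under a realistic data
distribution, not that any particular clinical effect size is reproduced —
in particular, the synthetic collective gains at sizes 4 and 8 remain
larger than those reported from real reader panels, because a single
distractor scalar only partially reproduces the error correlation of real
images.

## Numerical and degenerate-input choices

- All randomness flows from explicit integer seeds; the rater, image and
  rating streams of one cohort use `seed`, `seed + 1`, `seed + 2`, and the
  collective stage uses content-hashed substreams as above. Identical
  configuration and seed give byte-identical outputs.
- Confusion rows are validated to sum to 1 within 1e-9; the confident-state
  sharpening $1 - (1 - p_{ii})/b$ keeps rows exactly stochastic.
- `exact_collective_accuracy()` enumerates in log space (`lgamma`) to avoid
  overflow and is capped at $k \le 12$.
- Empty cells, images with zero answers in a cell, raters with zero valid
  ratings, and zero denominators in diagnostic metrics all propagate as
  omissions, warnings or `NA` — never silently as 0.
- Retention on an empty rater table and means over zero images raise
  errors, as no value is defensible.

## Problem sizes

The shipped tests simulate cohorts of 6–50 raters and 37–211 images
(thousands to ~10⁴ ratings), run bootstrap panels at $B$ between 100 and
100 000 where the exact oracle provides the reference, and verify the
expert/collective/confidence orderings over 10 independent seeds. The
`scripts/acceptance.R` entry point runs the full default pipeline
(211 images, $B = 1000$, sizes 3–8) in well under a minute.
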