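# crowddx

Collective-intelligence analysis for multirater skin lesion diagnosis.

Dermatoscopic diagnosis of pigmented skin lesions is a seven-class problem
(AKIEC, BCC, BKL, DF, MEL, NV, VASC) on which individual non-expert readers
are error-prone. A *virtual collective* asks several readers independently
and takes the category with the most votes — first-past-the-post, ties
broken at random — as the collective diagnosis. `crowddx` is for
biostatisticians and reader-study analysts who want to quantify how much a
collective of size *k* improves on single readers, and how answer-time
confidence stratification changes the picture.

The package provides, end to end:

- a **synthetic cohort generator** (raters in 5 experience groups with
  heterogeneous 7×7 confusion matrices, fixed 30-image batch composition,
  lognormal answer times with a 25-s timeout, per-image difficulty with a
  shared distractor category);
- the **cleaning filters** of gamified reader studies: invalid-answer
  removal, a 30-round cap per rater, exclusion of rounds with too few
  answers and of images with fewer than 8 ratings;
- **confidence labelling**: an answer is high-confidence iff its time ≤ the
  rater's own mean answer time;
- **bootstrap collectives**: for an image with answer pool *A* and size
  *k* ∈ {3,…,8}, each of *B* replicates draws *k* answers from *A* with
  replacement and votes; per-image accuracy is the fraction of replicates
  voting the truth. An exact multinomial enumeration oracle
  (`exact_collective_accuracy()`) gives the *B* → ∞ limit;
- **diagnostic metrics**: 7-class mean accuracy (images weighted equally),
  per-category sensitivity, and malignancy detection (malignant = {AKIEC,
  BCC, MEL}) as sensitivity/specificity/PPV/NPV with Wilson (or
  Clopper–Pearson / normal) 95% CIs;
- **inference**: paired *t* tests of per-image accuracy between cells over
  their overlapping images, with Bonferroni–Holm correction.

## Worked example

```r
library(crowddx)

cfg <- pipeline_config(seed = 42)           # defaults: ~50 raters, 211 images
cohort <- simulate_cohort(cfg$simulation)   # raters, images, ~5900 ratings
analysis <- analyze_cohort(cohort, cfg)

analysis$comparisons[, c("group", "k", "confidence", "mean_accuracy",
                         "mean_difference", "p_adjusted")]
```

```
# A tibble: 12 × 6
   group         k confidence mean_accuracy mean_difference p_adjusted
   <chr>     <int> <chr>              <dbl>           <dbl>      <dbl>
 1 nonexpert    NA all                 61.5           0      NA
 2 nonexpert    NA low                 59.8          -1.69    2.73e- 1
 3 nonexpert    NA high                62.2           0.703   2.73e- 1
 4 nonexpert     4 all                 74.9          13.4     6.66e-76
 5 nonexpert     4 low                 68.6           7.63    1.78e- 8
 6 nonexpert     4 high                73.7          12.2     1.30e-33
 7 nonexpert     8 all                 82.6          21.1     8.32e-72
 8 nonexpert     8 low                 77.8          18.0     8.67e-19
 9 nonexpert     8 high                83.0          20.4     2.99e-39
10 expert       NA all                 72.0          11.6     1.75e- 4
11 expert       NA low                 69.5           8.09    2.08e- 1
12 expert       NA high                72.5          13.2     4.10e- 4
```

Reading the table: single nonexperts get 61.5% of specific diagnoses right
on this synthetic cohort; a bootstrap collective of 4 nonexperts gains
+13.4 percentage points over them (paired over the same images,
Holm-adjusted p < 0.001), a collective of 8 gains +21.1, and single experts
gain +11.6 — the collective reaches and passes single-expert accuracy. Low
confidence (slow) answers score below the baseline. `analysis` also carries
`metrics_summary` (malignancy sensitivity/specificity/PPV/NPV per cell),
`category_sensitivity` (per-category accuracy vs collective size, the input
to `plot_category_sensitivity()`), and `collective_accuracy` (per-image
bootstrap results).

`run_pipeline(cfg, "out/")` writes the cohort CSVs, the four analysis
tables (with seed/config-hash provenance headers), `manifest.json` and a
markdown report. A thin CLI over the same functions is installed at
`inst/scripts/crowddx.R` (verbs `simulate`, `analyze`, `report`, `all`).

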