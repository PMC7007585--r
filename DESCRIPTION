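Package: crowddx
Title: Collective Intelligence Analysis for Multirater Skin Lesion Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses multirater reader studies of seven-class
    pigmented skin lesion diagnosis (AKIEC, BCC, BKL, DF, MEL, NV, VASC).
    Provides a synthetic cohort generator with heterogeneous rater accuracy,
    per-image difficulty and answer-time based confidence; the cleaning
    filters used in gamified reader studies (round caps, incomplete-round and
    sparse-image exclusion); bootstrap plurality-vote collectives of sizes 3
    to 8 with random tie-breaking and an exact enumeration oracle;
    specific-diagnosis and malignancy-detection metrics with binomial
    confidence intervals; and paired t comparisons of per-image accuracy with
    Holm correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
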