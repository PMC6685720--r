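Package: impactfa
Title: Head-Impact Exposure and Midbrain White-Matter Integrity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking helmet-accelerometer head-impact telemetry to
    longitudinal changes in white-matter fractional anisotropy (FA). Provides
    per-session exposure summaries, cohort-derived force thresholds
    (mean + 1 SD), suprathreshold and exclusive-threshold hit counts, decile
    threshold sweeps, and a 648-bin spherical histogram ("spatial
    fingerprint") of impact locations; atlas-driven region-of-interest
    construction (mask intersection, hemisphere split) and mean-FA extraction
    from NIfTI volumes in a shared standard space; paired and two-sample
    location tests, Spearman dose-response analysis, the hemispheric
    laterality index, and serum tau-FA association; and leave-one-out nu
    support-vector regression predicting laterality from spatial
    fingerprints, with permutation inference and a Bonferroni-thresholded
    per-bin relevance map. Includes a synthetic cohort generator with planted
    effects so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
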