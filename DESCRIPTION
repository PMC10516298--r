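Package: oculometrics
Title: Oculomotor Parameter Extraction and Clinical Association Analysis
    for Low-Rate Eye Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning raw 60 Hz gaze traces from a four-task
    oculomotor battery (fixation, pro-saccade, anti-saccade, step-ramp
    smooth pursuit) into a canonical set of twenty oculomotor parameters,
    and for relating those parameters to multiple-sclerosis clinical
    scores.  Includes a synthetic cohort generator with planted
    oculomotor ground truth, adaptive velocity-based saccade detection,
    parametric main-sequence waveform fitting, fixation-stability (BCEA)
    and smooth-pursuit metrics, BICAMS/MSFC composite construction,
    Spearman correlation screens with Benjamini-Hochberg control,
    EDSS subgroup contrasts, and partial least squares regression with
    cross-validated component selection and exhaustive feature search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
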