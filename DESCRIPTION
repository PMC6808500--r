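Package: walkvep
Title: Steady-State Visual Evoked Potential and Psychophysics Analysis for
    Free-Walking EEG Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mobile EEG/EOG experiments probing visual
    processing during free walking. Provides a synthetic-session generator with
    ground-truth events, Welch spectral estimation with neighbour-frequency
    referencing of steady-state visual evoked potential (SSVEP) and alpha power,
    ocular and head-movement artifact detection from EOG and gyroscope signals,
    robust MAD-median trial exclusion, transformed up/down adaptive staircases
    with a simulated observer, behavioural response scoring with a target
    preference index and its simulation null, and the within-subjects
    inferential layer (repeated-measures ANOVA with Greenhouse-Geisser
    correction, paired t tests, false-discovery-rate control, median-split and
    two-level regression analyses).
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
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
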