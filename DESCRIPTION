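Package: painbias
Title: Simulation and Analysis of Attention and Interpretation Bias in a
    Conditioned Pain-Cue Paradigm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for a fear-conditioning generalization paradigm in which
    participants perform a 2-back working-memory task while colour-graded
    conditioned cues signal possible painful stimulation.  The package
    generates the full experimental schedule (acquisition, booster, test and
    colour-discrimination phases), simulates per-participant raw data
    (area-of-interest gaze streams, binocular pupillometry, 2-back responses
    and numerical pain-threat ratings) with configurable injected bias
    effects, preprocesses the raw streams (gap reconstruction, fixation
    detection, median filtering, blink interpolation, baseline-corrected
    pupil dilation epochs, reaction-time cleaning), derives the seven
    ambiguous-versus-safe-cue difference indices of attention bias,
    interpretation bias and task interference, and runs the accompanying
    statistical battery (paired t tests with dz, Greenhouse-Geisser corrected
    repeated-measures ANOVA with partial eta squared, Friedman and Wilcoxon
    signed-rank tests, Pearson correlations with Fisher-z intervals,
    three-step hierarchical moderated regression with simple slopes, and
    exact power analysis for correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
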