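#' Full preprocessing and index derivation for one participant
#'
#' Runs the complete per-participant pathway on a raw record: gaze gap
#' reconstruction, fixation detection and attention metrics; pupil median
#' filtering, blink interpolation, fusion and the baseline-corrected 2-s
#' epoch dilation; 2-back reaction-time cleaning and scoring; trial-level
#' validity; category means over valid test trials; and the seven
#' ambiguous-minus-safe bias indices.  A trial counts as invalid for the
#' participant-level exclusion rule when it is invalid on either the gaze
#' or the pupil criterion.
#'
#' @param record A `participant_record` from [simulate_participant()].
#' @param config A [pipeline_config()] (preprocessing constants).
#' @return A one-row tibble: identifiers and demographics, `calibrated_mA`,
#'   `practice_attempts`, `color_accuracy`, post-acquisition check means,
#'   participant `valid` flag with `n_invalid_trials`, the per-category
#'   means of every metric (`<metric>_<category>` columns) and the seven
#'   bias indices.
#' @export
participant_indices <- function(record, config = pipeline_config()) {
  cfg <- config
  plan <- record$session
  test <- dplyr::filter(plan$trials, .data$phase == "TEST")
  durations <- dplyr::select(test, trial = "index", "duration_s")

  gm <- gaze_metrics(
    dplyr::semi_join(record$gaze, durations, by = "trial"),
    durations,
    min_fix_ms = cfg$min_fix_ms, max_gap_ms = cfg$max_gap_ms,
    max_missing = cfg$max_missing)
  pm <- pupil_metrics(
    dplyr::semi_join(record$pupil, durations, by = "trial"),
    cue_onset_ms = 4000, window = cfg$median_window,
    margin_ms = cfg$blink_margin_ms, max_blink_ms = cfg$max_blink_ms,
    baseline_ms = cfg$baseline_ms, epoch_ms = cfg$epoch_ms,
    max_missing = cfg$max_missing)
  beh <- behavior_metrics(
    dplyr::filter(dplyr::semi_join(record$behavior, durations, by = "trial"),
                  .data$pos >= 3L),
    dplyr::semi_join(record$ratings, durations, by = "trial"),
    sd_cutoff = cfg$rt_sd_cutoff)

  metrics <- gm |>
    dplyr::rename(gaze_valid = "valid") |>
    dplyr::full_join(dplyr::rename(pm, pupil_valid = "valid",
                                   pupil_missing_frac = "missing_frac"),
                     by = "trial") |>
    dplyr::full_join(beh, by = "trial")

  trial_invalid <- !(metrics$gaze_valid & metrics$pupil_valid)
  participant_valid <- participant_validity(!trial_invalid)

  cm <- category_means(metrics, plan)
  idx <- bias_indices(cm)
  acq <- acquisition_check(record$postacq)

  cm_wide <- cm |>
    dplyr::select(-"n_trials") |>
    tidyr::pivot_longer(-"category", names_to = "metric") |>
    dplyr::mutate(name = paste(.data$metric, .data$category, sep = "_")) |>
    dplyr::select("name", "value") |>
    tidyr::pivot_wider()

  dplyr::bind_cols(
    tibble::tibble(
      id = record$id, age = record$age, sex = record$sex,
      chronic_pain = record$chronic_pain,
      calibrated_mA = record$calibrated_mA,
      practice_attempts = record$practice_attempts,
      color_accuracy = color_accuracy(record$color),
      valid = participant_valid,
      n_invalid_trials = sum(trial_invalid)
    ),
    acq, cm_wide, idx
  )
}

#' Bias indices for every participant of a cohort
#'
#' @param cohort A `cohort` from [simulate_cohort()] (or any list of
#'   `participant_record`s).
#' @inheritParams participant_indices
#' @return A tibble with one row per participant (see
#'   [participant_indices()]).
#' @examples
#' \donttest{
#' coh <- simulate_cohort(3, seed = 1)
#' cohort_indices(coh)
#' }
#' @export
cohort_indices <- function(cohort, config = pipeline_config()) {
  purrr::map_dfr(cohort, participant_indices, config = config)
}

index_names <- function() {
  c("ab_cue_dwell", "ab_tablet_dwell", "ab_cue_fix", "ib_threat", "ib_pdr",
    "ti_latency", "ti_error")
}

#' Statistical battery over a cohort index table
#'
#' Reproduces the study's analysis pathway on a per-participant index
#' table:
#'
#' * manipulation checks: paired t (with dz) of post-acquisition CS+ vs
#'   CS- expectancy, and mean colour-discrimination accuracy;
#' * omnibus condition effects: Greenhouse-Geisser corrected
#'   repeated-measures ANOVAs (with partial eta squared and paired-t
#'   follow-ups) for pain threat, epoch pupil dilation, 2-back latency and
#'   error rate; Friedman tests with Wilcoxon signed-rank follow-ups for
#'   the three gaze metrics (whose residuals are treated as non-normal, as
#'   in the paradigm's analysis plan);
#' * Pearson correlations (Fisher-z 95% CIs) among the seven indices;
#' * three-step hierarchical moderated regressions of each
#'   task-interference outcome on every attention-bias index paired with
#'   the threat-rating interpretation-bias index, with simple slopes at
#'   +/-1 SD of the moderator for each interaction model.
#'
#' Participants flagged invalid or with chronic pain are excluded first; no
#' multiple-comparison correction is applied, matching the analysis plan.
#'
#' @param indices A tibble from [cohort_indices()].
#' @return An object of class `cohort_analysis`: a list with
#'   `manipulation`, `anovas`, `friedman`, `correlations`, `regressions`,
#'   `simple_slopes`, `exclusions`, and the analyzed table `data`.
#' @export
analyze_cohort <- function(indices) {
  n_in <- nrow(indices)
  excl_pain <- sum(indices$chronic_pain)
  d <- dplyr::filter(indices, !.data$chronic_pain)
  excl_valid <- sum(!d$valid)
  d <- dplyr::filter(d, .data$valid)
  d <- d[stats::complete.cases(d[index_names()]), ]
  excl_missing <- nrow(indices) - excl_pain - excl_valid - nrow(d)
  if (nrow(d) < 4L) stop("fewer than 4 analyzable participants", call. = FALSE)

  manipulation <- list(
    acquisition = paired_t(d$csplus_expectancy, d$csminus_expectancy),
    color_accuracy_mean = mean(d$color_accuracy),
    color_accuracy_sd = stats::sd(d$color_accuracy)
  )

  cat_cols <- function(metric) {
    m <- as.matrix(d[paste(metric, c("PAIN", "AMBIGUOUS", "NONPAIN"),
                           sep = "_")])
    colnames(m) <- c("cs_plus", "csa", "cs_minus")
    m[stats::complete.cases(m), , drop = FALSE]
  }
  anova_with_posthoc <- function(metric) {
    m <- cat_cols(metric)
    pairs <- utils::combn(colnames(m), 2L)
    list(
      omnibus = rm_anova(m),
      pairwise = purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
        ht <- paired_t(m[, pairs[1L, i]], m[, pairs[2L, i]])
        tibble::tibble(a = pairs[1L, i], b = pairs[2L, i], t = ht$t,
                       df = ht$df, p = ht$p, d_z = ht$d_z)
      }),
      means = colMeans(m), n = nrow(m)
    )
  }
  anovas <- list(
    pain_threat = anova_with_posthoc("pain_threat"),
    pdr = anova_with_posthoc("pdr_mm"),
    latency = anova_with_posthoc("mean_rt_ms"),
    error_rate = anova_with_posthoc("error_rate")
  )
  friedman <- list(
    cue_dwell = friedman_wilcoxon(cat_cols("cue_dwell_ms_per_s")),
    cue_fix = friedman_wilcoxon(cat_cols("cue_fixations_per_s")),
    tablet_dwell = friedman_wilcoxon(cat_cols("tablet_dwell_ms_per_s"))
  )

  idx <- index_names()
  pairs <- utils::combn(idx, 2L)
  correlations <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    dplyr::mutate(pearson_ci(d[[a]], d[[b]]), a = a, b = b, .before = 1L)
  })

  ab_indices <- c("ab_cue_dwell", "ab_tablet_dwell", "ab_cue_fix")
  outcomes <- c("ti_latency", "ti_error")
  grid <- tidyr::expand_grid(outcome = outcomes, ab = ab_indices)
  regressions <- purrr::pmap(grid, function(outcome, ab) {
    hierarchical_regression(d, outcome = outcome, ab = ab, ib = "ib_threat")
  })
  names(regressions) <- paste(grid$outcome, grid$ab, sep = "~")
  slopes <- purrr::map(regressions, simple_slopes)

  structure(
    list(manipulation = manipulation, anovas = anovas, friedman = friedman,
         correlations = correlations, regressions = regressions,
         simple_slopes = slopes,
         exclusions = tibble::tibble(
           n_in = n_in, chronic_pain = excl_pain, invalid_data = excl_valid,
           incomplete_indices = excl_missing, n_analyzed = nrow(d)),
         data = d),
    class = "cohort_analysis"
  )
}

#' @export
print.cohort_analysis <- function(x, ...) {
  e <- x$exclusions
  cat(sprintf(
    "<cohort_analysis> %d analyzed of %d (chronic pain %d, invalid %d, incomplete %d)\n",
    e$n_analyzed, e$n_in, e$chronic_pain, e$invalid_data,
    e$incomplete_indices))
  a <- x$manipulation$acquisition
  cat(sprintf("  acquisition check: t(%d) = %.2f, dz = %.2f\n",
              a$df, a$t, a$d_z))
  cat(sprintf("  colour accuracy: %.3f\n", x$manipulation$color_accuracy_mean))
  cat(sprintf("  threat rmANOVA: F(%.2f, %.2f) = %.2f, partial eta^2 = %.2f\n",
              x$anovas$pain_threat$omnibus$df1_gg,
              x$anovas$pain_threat$omnibus$df2_gg,
              x$anovas$pain_threat$omnibus$F,
              x$anovas$pain_threat$omnibus$partial_eta2))
  invisible(x)
}
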