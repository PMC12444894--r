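#' Generative parameters for a simulated participant
#'
#' Defaults reproduce the observed study conditions: cue-gaze occupancy and
#' the attention-bias increments are set so the implied cue/tablet dwell
#' rates match the reported category means (safe-cue dwell 1.25 ms/s, tablet
#' dwell 955.5 ms/s), threat ratings follow the reported category means
#' (safe 1.44, ambiguous +1.39, pain +4.48 on the 0-10 scale), 2-back
#' latencies are log-normal around 582 ms with category slowing of
#' +3.17 ms (ambiguous) and +8.63 ms (pain), and the pupil epoch effect for
#' ambiguous cues is -3.2e-3 mm (the reported near-null).  Effect
#' parameters are per-participant values; between-subject dispersion is
#' configured in [cohort_params()].
#'
#' Gaze is generated as a sequence of dwell episodes of `gaze_slot_ms`
#' each; each episode's area of interest is drawn independently with
#' `P(CUE) = base_cue_prob + ab_effect[category]`,
#' `P(OTHER) = base_other_prob + search_effect[category]`, remainder tablet.
#' Blinks hit both eyes and the gaze stream simultaneously; longer
#' tracker-loss episodes hit gaze only.
#'
#' @param ... Named overrides of any default listed below.
#' @return An object of class `participant_params` (a validated named list).
#' @examples
#' p <- participant_params(ib_threat_effect = 2)
#' p$ib_threat_effect
#' @export
participant_params <- function(...) {
  p <- list(
    sample_rate_hz = 120,
    gaze_slot_ms = 250,
    # gaze occupancy (probabilities per dwell episode)
    base_cue_prob = 0.00125,
    ab_effect = c(PAIN = 0.00127, AMBIGUOUS = 0.00053, NONPAIN = 0),
    base_other_prob = 0.04325,
    search_effect = c(PAIN = 0.01348, AMBIGUOUS = 0.00708, NONPAIN = 0),
    # threat ratings (0-10 NRS)
    base_threat = 1.44,
    ib_threat_effect = 1.39,
    csplus_threat_effect = 4.48,
    rating_noise_sd = 1.0,
    postacq_csplus_expectancy = 9.12,
    postacq_csminus_expectancy = 0.60,
    postacq_csplus_fear = 8.50,
    postacq_csminus_fear = 0.80,
    # pupil
    baseline_pupil_mm = 3.5,
    pupil_noise_sd_mm = 0.05,
    pupil_drift_amp_mm = 0.05,
    pdr_effect_mm = c(PAIN = 0, AMBIGUOUS = -0.00322, NONPAIN = 0),
    blink_rate_hz = 0.2,
    blink_dur_ms = c(100, 400),
    missing_episode_rate_hz = 0.02,
    missing_episode_dur_ms = c(600, 1500),
    # 2-back
    rt_median_ms = 582,
    rt_sdlog = 0.18,
    rt_slowing_ms = c(PAIN = 8.63, AMBIGUOUS = 3.17, NONPAIN = 0),
    base_error_rate = 0.05,
    error_effect = c(PAIN = 0.002, AMBIGUOUS = 0.00211, NONPAIN = 0),
    omission_prob = 0.02,
    target_prob = 0.3,
    response_window_ms = 1500,
    # colour discrimination and calibration
    color_accuracy = 0.95,
    pain_threshold_mA = 3.5,
    staircase_noise = 5,
    staircase_step_mA = 0.5,
    staircase_ceiling_mA = 10
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(dots)) {
    v <- dots[[nm]]
    if (is.numeric(p[[nm]]) && !is.null(names(p[[nm]]))) {
      # allow partial named overrides of category vectors
      if (is.null(names(v)) && length(v) == length(p[[nm]])) {
        names(v) <- names(p[[nm]])
        p[[nm]] <- v
      } else {
        p[[nm]][names(v)] <- v
      }
    } else {
      p[[nm]] <- v
    }
  }
  validate_participant_params(p)
  structure(p, class = "participant_params")
}

validate_participant_params <- function(p) {
  stopifnot(
    p$sample_rate_hz > 0, p$gaze_slot_ms > 0,
    p$base_cue_prob >= 0, p$base_other_prob >= 0,
    all(p$ab_effect + p$base_cue_prob >= 0),
    all(p$ab_effect + p$base_cue_prob + p$search_effect +
          p$base_other_prob <= 1),
    p$base_threat >= 0,
    p$base_threat + p$ib_threat_effect <= 10,
    p$base_threat + p$csplus_threat_effect <= 10,
    p$base_error_rate >= 0, p$base_error_rate <= 1,
    p$omission_prob >= 0, p$omission_prob < 1,
    p$baseline_pupil_mm > 1, p$baseline_pupil_mm < 9,
    p$pain_threshold_mA > 0
  )
  invisible(p)
}

#' Between-subject distribution of generative parameters
#'
#' Describes how [simulate_cohort()] perturbs the cohort-level
#' [participant_params()] per participant: gaze occupancies are scaled by
#' unit-mean log-normal multipliers (keeping probabilities positive and the
#' cohort-mean indices at their nominal values), additive effects get
#' normal between-subject deviations, and demographics follow the study
#' sample (age 21 +/- 5.5, 85% female, ~5% screened out for chronic pain).
#' Dispersion defaults are chosen so that the per-participant spread of
#' each derived index matches the reported index standard deviations.
#'
#' @param ... Named overrides of the defaults below.
#' @return An object of class `cohort_params` (a named list).
#' @export
cohort_params <- function(...) {
  b <- list(
    gaze_mult_sdlog = 0.6,
    search_mult_sdlog = 0.6,
    threat_base_sd = 1.2,
    ib_between_sd = 1.1,
    csplus_between_sd = 1.5,
    pdr_between_sd = 0.04,
    baseline_pupil_between_sd = 0.3,
    rt_base_sdlog = 0.21,
    rt_slow_between_sd = 18,
    error_base_sd = 0.02,
    error_between_sd = 0.0227,
    postacq_between_sd = 1.2,
    color_accuracy_sd = 0.04,
    age_mean = 21, age_sd = 5.5, age_range = c(18, 65),
    prop_female = 72 / 85,
    prop_chronic_pain = 5 / 92,
    threshold_sdlog = 0.25
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(b))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  b[names(dots)] <- dots
  structure(b, class = "cohort_params")
}

# Draw one participant's params from the between-subject distribution.
# Must be called with the RNG state already seeded by the caller.
draw_participant_params <- function(params, between) {
  p <- unclass(params)
  b <- between
  gm <- stats::rlnorm(1, -b$gaze_mult_sdlog^2 / 2, b$gaze_mult_sdlog)
  sm <- stats::rlnorm(1, -b$search_mult_sdlog^2 / 2, b$search_mult_sdlog)
  p$base_cue_prob <- p$base_cue_prob * gm
  p$ab_effect <- p$ab_effect * gm
  p$base_other_prob <- p$base_other_prob * sm
  p$search_effect <- p$search_effect * sm
  p$base_threat <- clip(p$base_threat + stats::rnorm(1, 0, b$threat_base_sd),
                        0, 5)
  p$ib_threat_effect <- p$ib_threat_effect +
    stats::rnorm(1, 0, b$ib_between_sd)
  p$csplus_threat_effect <- p$csplus_threat_effect +
    stats::rnorm(1, 0, b$csplus_between_sd)
  p$ib_threat_effect <- clip(p$ib_threat_effect, -p$base_threat,
                             10 - p$base_threat)
  p$csplus_threat_effect <- clip(p$csplus_threat_effect, -p$base_threat,
                                 10 - p$base_threat)
  for (nm in c("postacq_csplus_expectancy", "postacq_csminus_expectancy",
               "postacq_csplus_fear", "postacq_csminus_fear")) {
    p[[nm]] <- clip(p[[nm]] + stats::rnorm(1, 0, b$postacq_between_sd), 0, 10)
  }
  p$pdr_effect_mm <- p$pdr_effect_mm +
    stats::rnorm(length(p$pdr_effect_mm), 0, b$pdr_between_sd) *
    c(1, 1, 0)  # the safe-cue category stays the reference level
  p$baseline_pupil_mm <- clip(
    p$baseline_pupil_mm + stats::rnorm(1, 0, b$baseline_pupil_between_sd),
    1.5, 8.5)
  p$rt_median_ms <- p$rt_median_ms * stats::rlnorm(1, 0, b$rt_base_sdlog)
  p$rt_slowing_ms <- p$rt_slowing_ms +
    stats::rnorm(length(p$rt_slowing_ms), 0, b$rt_slow_between_sd) *
    c(1, 1, 0)
  p$base_error_rate <- clip(
    p$base_error_rate + stats::rnorm(1, 0, b$error_base_sd), 0.001, 0.5)
  p$error_effect <- p$error_effect +
    stats::rnorm(length(p$error_effect), 0, b$error_between_sd) * c(1, 1, 0)
  p$color_accuracy <- clip(
    p$color_accuracy + stats::rnorm(1, 0, b$color_accuracy_sd), 0.5, 1)
  p$pain_threshold_mA <- p$pain_threshold_mA *
    stats::rlnorm(1, 0, b$threshold_sdlog)
  class(p) <- "participant_params"
  p
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Model-implied cohort-mean bias indices
#'
#' The expected value of each of the seven derived indices under the
#' generative model with the given cohort-level parameters, used for
#' parameter-recovery checks.  Dwell indices are `1000 * dP(CUE)` (ms/s),
#' the tablet index is `-1000 * (dP(CUE) + dP(OTHER))`, the fixation-rate
#' index is `dP(CUE) * (1 - P) / slot` events per second (episodes of the
#' same AOI merge), and the rating, pupil and 2-back indices equal their
#' injected effects.
#'
#' @param params A [participant_params()] object.
#' @return A one-row tibble with the seven expected indices.
#' @export
implied_indices <- function(params) {
  p <- params
  slot_s <- p$gaze_slot_ms / 1000
  p_amb <- p$base_cue_prob + p$ab_effect[["AMBIGUOUS"]]
  p_non <- p$base_cue_prob + p$ab_effect[["NONPAIN"]]
  tibble::tibble(
    ab_cue_dwell = 1000 * (p_amb - p_non),
    ab_tablet_dwell = -1000 *
      ((p_amb - p_non) +
         (p$search_effect[["AMBIGUOUS"]] - p$search_effect[["NONPAIN"]])),
    ab_cue_fix = (p_amb * (1 - p_amb) - p_non * (1 - p_non)) / slot_s,
    ib_threat = p$ib_threat_effect,
    ib_pdr = p$pdr_effect_mm[["AMBIGUOUS"]] - p$pdr_effect_mm[["NONPAIN"]],
    ti_latency = p$rt_slowing_ms[["AMBIGUOUS"]] - p$rt_slowing_ms[["NONPAIN"]],
    ti_error = p$error_effect[["AMBIGUOUS"]] - p$error_effect[["NONPAIN"]]
  )
}
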