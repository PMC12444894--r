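#' Simulate the pain-calibration staircase
#'
#' The electrocutaneous stimulus intensity is calibrated with a simple
#' staircase starting at 0.5 mA and increasing in 0.5-mA steps; each
#' stimulus is rated on a 0-100 scale and the staircase stops at the first
#' current whose rating reaches or exceeds 80/100.  The procedure runs
#' three times and the highest stop current is used for the session.  The
#' simulated latent rating is `80 * I / pain_threshold_mA` plus Gaussian
#' noise (`staircase_noise`), clipped to the scale.
#'
#' @param params A [participant_params()] object.
#' @param seed Integer seed.
#' @param n_runs Number of staircase repetitions (default 3).
#' @return The calibrated current in mA.
#' @examples
#' simulate_staircase(participant_params(staircase_noise = 0), seed = 1)
#' @export
simulate_staircase <- function(params, seed, n_runs = 3L) {
  p <- params
  one_run <- function() {
    current <- p$staircase_step_mA
    repeat {
      rating <- clip(80 * current / p$pain_threshold_mA +
                       stats::rnorm(1, 0, p$staircase_noise), 0, 100)
      if (rating >= 80) return(current)
      current <- current + p$staircase_step_mA
      if (current > p$staircase_ceiling_mA) {
        stop("staircase reached the safety ceiling without an 80/100 rating",
             call. = FALSE)
      }
    }
  }
  withr::with_seed(as.integer(seed), max(vapply(seq_len(n_runs),
                                                function(i) one_run(),
                                                numeric(1L))))
}

# category-specific gaze episode probabilities
gaze_probs <- function(params, category) {
  p_cue <- params$base_cue_prob + params$ab_effect[[category]]
  p_other <- params$base_other_prob + params$search_effect[[category]]
  c(CUE = p_cue, TABLET = 1 - p_cue - p_other, OTHER = p_other)
}

# Poisson-placed interval events over [0, span_ms); returns matrix with
# columns start/end (ms)
draw_episodes <- function(rate_hz, dur_range_ms, span_ms) {
  n <- stats::rpois(1L, rate_hz * span_ms / 1000)
  if (n == 0L) return(cbind(start = numeric(0), end = numeric(0)))
  start <- stats::runif(n, 0, span_ms)
  dur <- stats::runif(n, dur_range_ms[1L], dur_range_ms[2L])
  cbind(start = start, end = pmin(start + dur, span_ms))
}

mark_intervals <- function(t_ms, episodes, offset_ms = 0) {
  hit <- rep(FALSE, length(t_ms))
  if (nrow(episodes) == 0L) return(hit)
  # first sample at or after each start, last sample strictly before each end
  a <- findInterval(episodes[, 1L] + offset_ms - 1e-9, t_ms) + 1L
  b <- findInterval(episodes[, 2L] + offset_ms - 1e-9, t_ms)
  for (i in seq_along(a)) if (a[i] <= b[i]) hit[a[i]:b[i]] <- TRUE
  hit
}

#' Simulate the raw data of one trial
#'
#' Generates the gaze stream (area-of-interest labels over the cue-present
#' window), the binocular pupil traces (from 2-back onset to trial end,
#' with a rectangular category-dependent dilation over the 2-s post-onset
#' epoch, slow drift, sensor noise and shared blinks), the 2-back letter
#' log with log-normal latencies slowed by the cue category, and the two
#' end-of-trial threat ratings (11-point NRS, rounded and clipped).
#' Blinks are mirrored in the gaze stream; longer tracker-loss episodes
#' affect gaze only.  Must be called with the RNG already seeded (the
#' participant- and cohort-level wrappers do this).
#'
#' @param plan_row One row of a session plan's `trials` tibble (non-practice).
#' @param params A [participant_params()] object.
#' @return A list with tibbles `gaze` (`t_ms`, `target`), `pupil` (`t_ms`,
#'   `left_mm`, `right_mm`), `behavior` (`pos`, `letter`, `is_target`,
#'   `response`, `correct`, `rt_ms`), `ratings` (`expectancy`, `fear`) and
#'   the flag `pain_delivered`.
#' @export
simulate_trial <- function(plan_row, params) {
  s <- simulate_trial_core(plan_row, params)
  list(
    gaze = if (is.null(s$gaze)) NULL else tibble::as_tibble(s$gaze),
    pupil = if (is.null(s$pupil)) NULL else tibble::as_tibble(s$pupil),
    behavior = if (is.null(s$behavior)) NULL else tibble::as_tibble(s$behavior),
    ratings = tibble::as_tibble(s$ratings),
    pain_delivered = s$pain_delivered
  )
}

simulate_trial_core <- function(plan_row, params) {
  stopifnot(plan_row$phase != "PRACTICE")
  p <- params
  category <- plan_row$category
  onset <- plan_row$cue_onset_ms
  end_ms <- onset + plan_row$duration_s * 1000
  period <- 1000 / p$sample_rate_hz
  eye_track <- plan_row$phase %in% c("TEST", "BOOSTER")

  gaze <- pupil <- NULL
  if (eye_track) {
    blinks <- draw_episodes(p$blink_rate_hz, p$blink_dur_ms, end_ms)

    # gaze: dwell episodes of gaze_slot_ms over the cue-present window
    t_gaze <- seq(onset, end_ms - period / 2, by = period)
    n_slots <- ceiling((end_ms - onset) / p$gaze_slot_ms)
    probs <- gaze_probs(p, category)
    slot_lab <- sample(names(probs), n_slots, replace = TRUE, prob = probs)
    target <- slot_lab[pmin(n_slots, floor((t_gaze - onset) /
                                             p$gaze_slot_ms) + 1L)]
    losses <- draw_episodes(p$missing_episode_rate_hz,
                            p$missing_episode_dur_ms, end_ms)
    target[mark_intervals(t_gaze, blinks) |
             mark_intervals(t_gaze, losses)] <- "MISSING"
    gaze <- list(t_ms = t_gaze, target = target)

    # pupil: covers the whole task so the pre-onset baseline exists
    t_pup <- seq(0, end_ms - period / 2, by = period)
    drift_phase <- stats::runif(1, 0, 2 * pi)
    base_sig <- p$baseline_pupil_mm +
      p$pupil_drift_amp_mm * sin(2 * pi * t_pup / 30000 + drift_phase) +
      p$pdr_effect_mm[[category]] * (t_pup >= onset & t_pup < onset + 2000)
    blink_hit <- mark_intervals(t_pup, blinks)
    eye <- function(offset) {
      v <- base_sig + offset + stats::rnorm(length(t_pup), 0,
                                            p$pupil_noise_sd_mm)
      v[blink_hit] <- NA_real_
      v
    }
    pupil <- list(t_ms = t_pup, left_mm = eye(-0.03), right_mm = eye(0.03))
  }

  behavior <- NULL
  if (plan_row$n_letters >= 3L) {
    behavior <- simulate_two_back(plan_row$n_letters, p,
                                  slowing_ms = p$rt_slowing_ms[[category]],
                                  extra_error = p$error_effect[[category]])
  }

  threat_mean <- p$base_threat + switch(category,
                                        PAIN = p$csplus_threat_effect,
                                        AMBIGUOUS = p$ib_threat_effect,
                                        NONPAIN = 0)
  rate_nrs <- function(mu) {
    round(clip(mu + stats::rnorm(1, 0, p$rating_noise_sd), 0, 10))
  }
  ratings <- list(expectancy = rate_nrs(threat_mean),
                  fear = rate_nrs(threat_mean))

  list(gaze = gaze, pupil = pupil, behavior = behavior, ratings = ratings,
       pain_delivered = isTRUE(plan_row$reinforced))
}

# 2-back letter log: targets placed with probability target_prob from
# position 3; responses correct with the category-adjusted probability,
# omitted with omission_prob, latencies log-normal plus category slowing,
# presses later than the response window become omissions.
simulate_two_back <- function(n_letters, params, slowing_ms = 0,
                              extra_error = 0) {
  p <- params
  letters_pool <- LETTERS
  letter <- character(n_letters)
  is_target <- logical(n_letters)
  letter[1:2] <- sample(letters_pool, 2L, replace = TRUE)
  for (i in 3:n_letters) {
    is_target[i] <- stats::runif(1) < p$target_prob
    letter[i] <- if (is_target[i]) letter[i - 2L] else
      sample(setdiff(letters_pool, letter[i - 2L]), 1L)
  }
  n_sc <- n_letters - 2L
  err_prob <- clip(p$base_error_rate + extra_error, 0.001, 0.5)
  omitted <- stats::runif(n_sc) < p$omission_prob
  correct <- stats::runif(n_sc) >= err_prob
  meanlog <- log(p$rt_median_ms)
  rt <- stats::rlnorm(n_sc, meanlog, p$rt_sdlog) + slowing_ms
  late <- rt > p$response_window_ms
  none <- omitted | late
  truth <- ifelse(is_target[-(1:2)], "SAME", "DIFFERENT")
  flip <- ifelse(truth == "SAME", "DIFFERENT", "SAME")
  response <- ifelse(none, "NONE", ifelse(correct, truth, flip))
  list(
    pos = seq_len(n_letters),
    letter = letter,
    is_target = is_target,
    response = c("NONE", "NONE", response),
    correct = c(FALSE, FALSE, !none & correct),
    rt_ms = c(NA_real_, NA_real_, ifelse(none, NA_real_, rt))
  )
}

#' Simulate a complete participant
#'
#' Builds the participant's session plan, runs the practice gate (repeating
#' the practice block until 70% accuracy is reached), the calibration
#' staircase, every acquisition/booster/test trial, the post-acquisition
#' ratings and the colour-discrimination responses.  Identical
#' `(params, seed)` give byte-identical records.
#'
#' @param params A [participant_params()] object (already participant-
#'   specific when called from [simulate_cohort()]).
#' @param seed Integer seed.
#' @param id Participant identifier.
#' @param counterbalance Gradient counterbalance flag for the session plan.
#' @param age,sex,chronic_pain Demographics attached to the record (defaults
#'   are placeholders; [simulate_cohort()] draws them).
#' @return An object of class `participant_record`: a list with the fields
#'   `id`, `age`, `sex`, `chronic_pain`, `calibrated_mA`, `session`
#'   (a `session_plan`), long tibbles `gaze`, `pupil`, `behavior`,
#'   `ratings` (all keyed by `trial` = the plan's trial `index`),
#'   `postacq`, `color`, `practice`, `practice_attempts`, and the `params`
#'   used.
#' @examples
#' rec <- simulate_participant(participant_params(), seed = 7)
#' dplyr::count(rec$gaze, target = rec$gaze$target == "MISSING")
#' @export
simulate_participant <- function(params = participant_params(), seed,
                                 id = 1L, counterbalance = FALSE,
                                 age = 21, sex = 0L, chronic_pain = FALSE) {
  seed <- as.integer(seed)
  plan <- build_session(seed = seed, counterbalance = counterbalance)
  calibrated <- simulate_staircase(params, seed = seed + 1L)

  withr::with_seed(seed + 2L, {
    # practice with gate
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      practice <- tibble::as_tibble(simulate_two_back(32L, params))
      if (practice_gate(practice$correct[-(1:2)]) || attempts >= 10L) break
    }

    non_practice <- dplyr::filter(plan$trials, .data$phase != "PRACTICE")
    sims <- lapply(seq_len(nrow(non_practice)), function(i) {
      simulate_trial_core(non_practice[i, ], params)
    })
    idx <- non_practice$index
    bind_stream <- function(field) {
      keep <- which(!vapply(sims, function(s) is.null(s[[field]]),
                            logical(1L)))
      if (!length(keep)) return(tibble::tibble())
      parts <- lapply(sims[keep], `[[`, field)
      lens <- vapply(parts, function(p) length(p[[1L]]), integer(1L))
      cols <- lapply(names(parts[[1L]]), function(nm) {
        unlist(lapply(parts, `[[`, nm), use.names = FALSE)
      })
      names(cols) <- names(parts[[1L]])
      tibble::as_tibble(c(list(trial = rep(idx[keep], lens)), cols))
    }
    gaze <- bind_stream("gaze")
    pupil <- bind_stream("pupil")
    behavior <- bind_stream("behavior")
    ratings <- bind_stream("ratings")

    # post-acquisition ratings of the four conditioned cues
    cond <- dplyr::filter(plan$cues, .data$category != "AMBIGUOUS")
    postacq <- dplyr::mutate(
      cond,
      expectancy = round(clip(ifelse(
        .data$category == "PAIN", params$postacq_csplus_expectancy,
        params$postacq_csminus_expectancy) +
          stats::rnorm(nrow(cond), 0, params$rating_noise_sd), 0, 10)),
      fear = round(clip(ifelse(
        .data$category == "PAIN", params$postacq_csplus_fear,
        params$postacq_csminus_fear) +
          stats::rnorm(nrow(cond), 0, params$rating_noise_sd), 0, 10))
    )

    color <- dplyr::mutate(
      plan$color_pairs,
      correct = stats::runif(dplyr::n()) < params$color_accuracy,
      responded_same = ifelse(.data$correct, .data$same_expected,
                              !.data$same_expected)
    )
  })

  structure(
    list(id = id, age = age, sex = sex, chronic_pain = chronic_pain,
         calibrated_mA = calibrated, session = plan, gaze = gaze,
         pupil = pupil, behavior = behavior, ratings = ratings,
         postacq = postacq, color = color, practice = practice,
         practice_attempts = attempts, params = params),
    class = "participant_record"
  )
}

#' @export
print.participant_record <- function(x, ...) {
  cat(sprintf(
    "<participant_record> id %s: %d trials, %d gaze samples, %.1f mA\n",
    x$id, sum(x$session$trials$phase != "PRACTICE"), nrow(x$gaze),
    x$calibrated_mA))
  invisible(x)
}

#' Simulate a cohort of participants
#'
#' Draws per-participant generative parameters from the between-subject
#' distribution, demographics from the study sample profile (age, sex,
#' chronic-pain screen), alternates the gradient counterbalance, and
#' simulates each participant with an independent derived seed.
#'
#' @param n Number of participants (>= 1).
#' @param params Cohort-level [participant_params()].
#' @param between A [cohort_params()] object.
#' @param seed Integer master seed; all per-participant seeds derive from it.
#' @return An object of class `cohort`: a list of `participant_record`s
#'   with attributes `seed`, `params`, `between`.
#' @examples
#' coh <- simulate_cohort(2, seed = 1)
#' length(coh)
#' @export
simulate_cohort <- function(n, params = participant_params(),
                            between = cohort_params(), seed = 1L) {
  stopifnot(n >= 1L)
  draws <- withr::with_seed(as.integer(seed), {
    list(
      seeds = sample.int(.Machine$integer.max - 10L, n),
      age = clip(round(stats::rnorm(n, between$age_mean, between$age_sd)),
                 between$age_range[1L], between$age_range[2L]),
      sex = as.integer(stats::runif(n) >= between$prop_female),
      chronic = stats::runif(n) < between$prop_chronic_pain,
      pp = lapply(seq_len(n), function(i)
        draw_participant_params(params, between))
    )
  })
  records <- lapply(seq_len(n), function(i) {
    simulate_participant(
      params = draws$pp[[i]], seed = draws$seeds[i], id = i,
      counterbalance = i %% 2L == 0L,
      age = draws$age[i], sex = draws$sex[i],
      chronic_pain = draws$chronic[i])
  })
  structure(records, class = "cohort", seed = as.integer(seed),
            params = params, between = between)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d simulated participants (seed %d)\n",
              length(x), attr(x, "seed")))
  invisible(x)
}
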