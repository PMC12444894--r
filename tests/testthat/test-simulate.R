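test_that("the staircase stops at the first 80/100 rating and takes the run maximum", {
  # noiseless: rating crosses 80 exactly at the threshold current
  p <- participant_params(staircase_noise = 0, pain_threshold_mA = 3.5)
  expect_equal(simulate_staircase(p, seed = 1), 3.5)
  # a threshold below the first step stops immediately at 0.5 mA
  p <- participant_params(staircase_noise = 0, pain_threshold_mA = 0.3)
  expect_equal(simulate_staircase(p, seed = 1), 0.5)
  # noisy runs: the result is the maximum over the three stop currents,
  # reproducible under the seed and on the 0.5-mA grid
  p <- participant_params(staircase_noise = 8, pain_threshold_mA = 3.5)
  stops <- withr::with_seed(5L, {
    vapply(1:3, function(i) {
      current <- 0.5
      repeat {
        rating <- min(max(80 * current / 3.5 + rnorm(1, 0, 8), 0), 100)
        if (rating >= 80) return(current)
        current <- current + 0.5
      }
    }, numeric(1L))
  })
  expect_equal(simulate_staircase(p, seed = 5), max(stops))
  # a degenerate threshold never reaches the criterion
  p <- participant_params(staircase_noise = 0, pain_threshold_mA = 500)
  expect_error(simulate_staircase(p, seed = 1), "ceiling")
})

test_that("identical parameters and seed give byte-identical records", {
  p <- fast_params()
  expect_identical(simulate_participant(p, seed = 13),
                   simulate_participant(p, seed = 13))
  expect_identical(simulate_cohort(3, p, seed = 2),
                   simulate_cohort(3, p, seed = 2))
})

test_that("null effects give identical gaze distributions for ambiguous and safe cues", {
  p <- null_effect_params()
  expect_equal(painbias:::gaze_probs(p, "AMBIGUOUS"),
               painbias:::gaze_probs(p, "NONPAIN"))
})

test_that("a constructed pupil bump is recovered exactly without noise", {
  p <- fast_params(pdr_effect_mm = c(AMBIGUOUS = 0.2),
                   pupil_noise_sd_mm = 0, pupil_drift_amp_mm = 0,
                   blink_rate_hz = 0)
  plan_row <- tibble::tibble(
    phase = "TEST", index = 1L, cue_id = "CS4", gradient_pos = 4L,
    category = "AMBIGUOUS", trajectory_id = 1L, duration_s = 16,
    reinforced = FALSE, n_letters = 10L, cue_onset_ms = 4000)
  s <- withr::with_seed(1, simulate_trial(plan_row, p))
  m <- epoch_pdr(s$pupil$left_mm, s$pupil$right_mm, s$pupil$t_ms, 4000)
  expect_equal(m$pdr_mm, 0.2)
})

test_that("the injected cue-gaze probability is recovered from the emitted stream", {
  # per-sample dwell episodes (slot = sample period) make the stream iid
  p <- fast_params(gaze_slot_ms = 1000 / 60,
                   base_cue_prob = 0.30,
                   ab_effect = c(PAIN = 0, AMBIGUOUS = 0.05, NONPAIN = 0),
                   blink_rate_hz = 0, missing_episode_rate_hz = 0)
  plan_row <- tibble::tibble(
    phase = "TEST", index = 1L, cue_id = "CS4", gradient_pos = 4L,
    category = "AMBIGUOUS", trajectory_id = 8L, duration_s = 58,
    reinforced = FALSE, n_letters = 31L, cue_onset_ms = 4000)
  frac <- withr::with_seed(2, {
    mean(vapply(1:3, function(i) {
      s <- simulate_trial(plan_row, p)
      mean(s$gaze$target == "CUE")
    }, numeric(1L)))
  })
  n <- 3 * 58 * 60
  expect_lt(abs(frac - 0.35), 3 * sqrt(0.35 * 0.65 / n))
})

test_that("trial records respect the response-window and reinforcement contracts", {
  p <- fast_params()
  rec <- simulate_participant(p, seed = 31)
  beh <- rec$behavior
  expect_true(all(is.na(beh$rt_ms) | beh$rt_ms <= 1500))
  expect_true(all(is.na(beh$rt_ms[beh$response == "NONE"])))
  expect_true(all(!is.na(beh$rt_ms[beh$response != "NONE"])))
  # ratings live on the 11-point scale
  expect_true(all(rec$ratings$expectancy %in% 0:10))
  expect_true(all(rec$ratings$fear %in% 0:10))
  # a record exists for every non-practice planned trial
  non_practice <- rec$session$trials$index[rec$session$trials$phase != "PRACTICE"]
  expect_setequal(unique(rec$ratings$trial), non_practice)
  # eye tracking covers booster + test only
  et <- rec$session$trials$index[rec$session$trials$phase %in%
                                   c("TEST", "BOOSTER")]
  expect_setequal(unique(rec$gaze$trial), et)
  # pupil sizes plausible when present
  expect_true(all(is.na(rec$pupil$left_mm) |
                    (rec$pupil$left_mm > 1 & rec$pupil$left_mm < 9)))
})

test_that("injected effects are recovered in sign by the derived indices", {
  p <- fast_params(
    ab_effect = c(PAIN = 0.02, AMBIGUOUS = 0.012, NONPAIN = 0),
    search_effect = c(PAIN = 0.05, AMBIGUOUS = 0.03, NONPAIN = 0),
    ib_threat_effect = 2)
  between <- cohort_params(gaze_mult_sdlog = 0.1, search_mult_sdlog = 0.1,
                           ib_between_sd = 0.3)
  coh <- simulate_cohort(8, p, between, seed = 7)
  idx <- cohort_indices(coh)
  expect_gt(mean(idx$ab_cue_dwell), 0)
  expect_gt(mean(idx$ab_cue_fix), 0)
  expect_lt(mean(idx$ab_tablet_dwell), 0)
  expect_gt(mean(idx$ib_threat), 0)
  # strong acquisition separation
  expect_gt(mean(idx$csplus_expectancy), mean(idx$csminus_expectancy) + 5)
})
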