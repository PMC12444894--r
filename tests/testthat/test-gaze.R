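period120 <- 1000 / 120

make_stream <- function(labels, period = period120) {
  tibble::tibble(t_ms = (seq_along(labels) - 1L) * period, target = labels)
}

test_that("gap reconstruction carries the preceding target over short gaps only", {
  # 48 samples at 120 Hz = 400 ms: reconstructed with the preceding label
  s <- make_stream(rep(c("TABLET", "MISSING", "CUE"), c(60, 48, 60)))
  r <- reconstruct_gaps(s)
  expect_equal(r$target, rep(c("TABLET", "CUE"), c(108, 60)))

  # 72 samples = 600 ms: stays missing
  s <- make_stream(rep(c("TABLET", "MISSING", "CUE"), c(60, 72, 60)))
  expect_equal(reconstruct_gaps(s)$target, s$target)

  # boundary: 60 samples = 500 ms reconstructed, 61 samples = 508 ms not
  s60 <- make_stream(rep(c("CUE", "MISSING", "CUE"), c(30, 60, 30)))
  expect_false(any(reconstruct_gaps(s60)$target == "MISSING"))
  s61 <- make_stream(rep(c("CUE", "MISSING", "CUE"), c(30, 61, 30)))
  expect_equal(sum(reconstruct_gaps(s61)$target == "MISSING"), 61L)

  # a leading gap has no preceding sample and stays missing
  s <- make_stream(rep(c("MISSING", "CUE"), c(20, 40)))
  expect_equal(sum(reconstruct_gaps(s)$target == "MISSING"), 20L)

  # identity on complete streams
  s <- make_stream(rep(c("CUE", "TABLET"), c(50, 50)))
  expect_identical(reconstruct_gaps(s), s)
})

test_that("gap reconstruction is idempotent and never edits valid samples", {
  withr::with_seed(11, {
    for (i in 1:25) {
      s <- random_stream(sample(100:400, 1L), period120)
      r1 <- reconstruct_gaps(s)
      expect_identical(reconstruct_gaps(r1), r1)
      keep <- s$target != "MISSING"
      expect_identical(r1$target[keep], s$target[keep])
    }
  })
})

test_that("fixations are maximal same-AOI runs of at least 100 ms", {
  # 11 samples at 120 Hz (91.7 ms) fall short of the threshold
  s <- make_stream(rep(c("TABLET", "CUE", "TABLET"), c(120, 11, 120)))
  expect_false("CUE" %in% detect_fixations(s)$aoi)
  # 12 samples (100.0 ms) reach it (inclusive threshold)
  s <- make_stream(rep(c("TABLET", "CUE", "TABLET"), c(120, 12, 120)))
  expect_equal(sum(detect_fixations(s)$aoi == "CUE"), 1L)

  # two maximal runs give two events
  s <- make_stream(rep(c("CUE", "TABLET"), c(120, 120)))
  fx <- detect_fixations(s)
  expect_equal(fx$aoi, c("CUE", "TABLET"))
  expect_equal(fx$duration_ms, c(1000, 1000))

  # missing never produces an event
  s <- make_stream(rep("MISSING", 240))
  expect_equal(nrow(detect_fixations(s)), 0L)
})

test_that("fixation detection matches the brute-force scan on random streams", {
  withr::with_seed(21, {
    for (i in 1:60) {
      period <- sample(c(1000 / 120, 1000 / 60, 20), 1L)
      s <- random_stream(sample(50:600, 1L), period)
      got <- detect_fixations(s)
      want <- slow_fixations(s$target, s$t_ms, period)
      expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
    }
  })
})

test_that("attention metrics normalize dwell and fixation counts by duration", {
  # 16-s trial with a single 4-s cue fixation
  s <- make_stream(rep(c("CUE", "TABLET"), c(480, 1440)))
  m <- attention_metrics(s, trial_duration_s = 16)
  expect_equal(m$cue_dwell_ms_per_s, 250)
  expect_equal(m$cue_fixations_per_s, 1 / 16)
  expect_true(m$valid)

  # gazing at the tablet throughout saturates at 1000 ms/s
  s <- make_stream(rep("TABLET", 1920))
  expect_equal(attention_metrics(s, 16)$tablet_dwell_ms_per_s, 1000)

  # 60% missing after reconstruction invalidates the trial
  s <- make_stream(rep(c("TABLET", "MISSING"), c(768, 1152)))
  expect_false(attention_metrics(s, 16)$valid)
  # exactly 50% missing is retained (strict rule)
  s <- make_stream(rep(c("TABLET", "MISSING"), c(960, 960)))
  expect_true(attention_metrics(s, 16)$valid)

  expect_error(attention_metrics(make_stream(character(0)), 16), "empty")
})

test_that("per-AOI dwell rates sum to at most 1000 ms/s", {
  withr::with_seed(31, {
    for (i in 1:20) {
      s <- random_stream(sample(200:800, 1L), period120, p_missing = 0.1)
      s <- reconstruct_gaps(s)
      m <- attention_metrics(s)
      fx <- detect_fixations(s)
      other <- sum(fx$duration_ms[fx$aoi == "OTHER"]) /
        (nrow(s) * period120 / 1000)
      total <- m$cue_dwell_ms_per_s + m$tablet_dwell_ms_per_s + other
      expect_lte(total, 1000 + 1e-9)
    }
  })
})

test_that("metrics are invariant to sample-rate refinement", {
  labels <- rep(c("CUE", "TABLET", "OTHER", "TABLET"), c(3, 10, 2, 9))
  coarse <- make_stream(rep(labels, each = 3L), period = 250 / 3)
  fine <- make_stream(rep(labels, each = 30L), period = 25 / 3)
  mc <- attention_metrics(coarse, trial_duration_s = 6)
  mf <- attention_metrics(fine, trial_duration_s = 6)
  expect_equal(mc$cue_dwell_ms_per_s, mf$cue_dwell_ms_per_s)
  expect_equal(mc$cue_fixations_per_s, mf$cue_fixations_per_s)
  expect_equal(mc$tablet_dwell_ms_per_s, mf$tablet_dwell_ms_per_s)
})
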