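period120 <- 1000 / 120

test_that("median smoothing removes spikes, keeps constants, rejects even windows", {
  expect_equal(median_smooth(rep(3, 50)), rep(3, 50))
  x <- rep(3, 21); x[11] <- 9
  expect_equal(median_smooth(x, 11), rep(3, 21))
  expect_error(median_smooth(1:10, 4), "odd")
  # missing samples stay missing; an isolated valid sample in a missing
  # neighbourhood keeps its own value (window has one non-missing entry)
  x <- c(NA, NA, 5, NA, NA)
  expect_equal(median_smooth(x, 3), c(NA, NA, 5, NA, NA))
})

test_that("median smoothing matches the sort-based oracle on random series", {
  withr::with_seed(41, {
    for (i in 1:40) {
      n <- sample(30:200, 1L)
      x <- rnorm(n, 3.5, 0.3)
      x[sample(n, round(n * 0.15))] <- NA
      w <- sample(c(3, 5, 11), 1L)
      expect_equal(median_smooth(x, w), slow_median(x, w))
    }
  })
})

test_that("deblink interpolates margined short blinks linearly and leaves long runs", {
  # 300-ms blink (36 samples at 120 Hz) between plateaus 3.0 and 3.5:
  # the margined span is one straight line between its anchors
  x <- c(rep(3, 60), rep(NA, 36), rep(3.5, 60))
  y <- deblink(x, period_ms = period120)
  expect_false(anyNA(y))
  margin_n <- ceiling(100 / period120)
  span <- (60 - margin_n + 1):(96 + margin_n)
  expect_equal(y[span],
               3 + 0.5 * seq_along(span) / (length(span) + 1L))
  expect_equal(y[1:(60 - margin_n)], rep(3, 60 - margin_n))
  expect_equal(y[(97 + margin_n):156], rep(3.5, 156 - 96 - margin_n))

  # 700-ms run (84 samples) is not a blink: untouched
  x <- c(rep(3, 60), rep(NA, 84), rep(3.5, 60))
  expect_equal(deblink(x, period_ms = period120), x)

  # boundary: 60 samples = 500 ms interpolated, 61 samples not
  x60 <- c(rep(3, 60), rep(NA, 60), rep(3.5, 60))
  expect_false(anyNA(deblink(x60, period_ms = period120)))
  x61 <- c(rep(3, 60), rep(NA, 61), rep(3.5, 60))
  expect_equal(sum(is.na(deblink(x61, period_ms = period120))), 61L)

  # identity without missing data
  x <- rnorm(100, 3.5, 0.1)
  expect_identical(deblink(x, period_ms = period120), x)

  # a blink at the trial edge has no anchor on one side and stays missing
  x <- c(rep(NA, 24), rep(3.4, 100))
  y <- deblink(x, period_ms = period120)
  expect_true(all(is.na(y[1:24])))
})

test_that("deblink never edits valid samples outside margined spans and stays within anchors", {
  withr::with_seed(51, {
    for (i in 1:25) {
      n <- 400
      x <- rnorm(n, 3.5, 0.2)
      # plant a few candidate blinks of varied length
      for (k in 1:3) {
        at <- sample(50:(n - 80), 1L)
        len <- sample(5:80, 1L)
        x[at:(at + len)] <- NA
      }
      y <- deblink(x, period_ms = period120)
      margin_n <- ceiling(100 / period120)
      # samples further than the margin from any missing sample are untouched
      na_idx <- which(is.na(x))
      protected <- setdiff(seq_len(n), unique(unlist(
        lapply(na_idx, function(j) (j - margin_n):(j + margin_n)))))
      expect_identical(y[protected], x[protected])
      # interpolated values lie within the range of the valid values
      filled <- which(is.na(x) & !is.na(y))
      if (length(filled)) {
        expect_true(all(y[filled] >= min(x, na.rm = TRUE) - 1e-12))
        expect_true(all(y[filled] <= max(x, na.rm = TRUE) + 1e-12))
      }
    }
  })
})

test_that("epoch PDR is the baseline-corrected epoch mean of the fused eyes", {
  t <- seq(0, 8000 - 1, by = period120)
  const <- rep(3, length(t))
  m <- epoch_pdr(const, const, t, cue_onset_ms = 4000)
  expect_equal(m$baseline_mm, 3)
  expect_equal(m$pdr_mm, 0)
  expect_true(m$valid)

  # constructed 0.2-mm bump over the epoch
  bump <- 3 + 0.2 * (t >= 4000 & t < 6000)
  m <- epoch_pdr(bump, bump, t, cue_onset_ms = 4000)
  expect_equal(m$pdr_mm, 0.2)

  # offset invariance: adding a constant to both eyes leaves the PDR alone
  m2 <- epoch_pdr(bump + 1.3, bump + 1.3, t, cue_onset_ms = 4000)
  expect_equal(m2$pdr_mm, m$pdr_mm)

  # a fully missing baseline window invalidates the trial
  miss <- const
  miss[t >= 3900 & t < 4000] <- NA
  m <- epoch_pdr(miss, miss, t, cue_onset_ms = 4000)
  expect_false(m$valid)
  expect_true(is.na(m$pdr_mm))

  # fusion with one eye entirely missing equals the other eye's trace
  left <- 3 + 0.1 * sin(t / 500)
  m1 <- epoch_pdr(left, rep(NA_real_, length(t)), t, 4000)
  m2 <- epoch_pdr(left, left, t, 4000)
  expect_equal(m1$pdr_mm, m2$pdr_mm)
  expect_equal(m1$baseline_mm, m2$baseline_mm)

  expect_error(epoch_pdr(const, const, t, cue_onset_ms = 9000), "onset")
})

test_that("participant validity uses a strict over-50% rule", {
  expect_true(participant_validity(rep(c(TRUE, FALSE), c(28, 28))))
  expect_false(participant_validity(rep(c(TRUE, FALSE), c(27, 29))))
  expect_true(participant_validity(rep(TRUE, 56)))
})
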