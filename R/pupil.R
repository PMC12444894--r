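#' Median-smooth a pupil trace
#'
#' Centered running median (default window 11 samples) applied per eye
#' before blink handling.  Missing samples stay missing, so blink episodes
#' are preserved exactly; elsewhere the median is taken over the non-missing
#' values in the window, with shrunken windows at the edges.
#'
#' @param x Numeric vector of pupil diameters (mm), `NA` = missing.
#' @param window Odd positive integer window size (samples).
#' @return Smoothed numeric vector, same length and missingness as `x`.
#' @examples
#' median_smooth(c(3, 3, 9, 3, 3), window = 3)
#' @export
median_smooth <- function(x, window = 11L) {
  if (length(window) != 1L || window < 1 || window %% 2 == 0) {
    stop("`window` must be a positive odd integer", call. = FALSE)
  }
  running_median_na(as.numeric(x), as.integer(window))
}

#' Remove blinks from a pupil trace
#'
#' Each maximal missing run of at most `max_blink_ms` (500 ms) is treated as
#' a blink: margins of `margin_ms` (100 ms) before and after it are
#' discarded, and the margined span is filled by linear interpolation
#' between the nearest valid neighbours.  Overlapping margined spans merge.
#' Missing runs longer than `max_blink_ms` are left missing, as are blinks
#' abutting the trial edge with no valid neighbour on one side.
#'
#' @param x Numeric vector (one eye, already median-smoothed), `NA` = missing.
#' @param period_ms Sample period in milliseconds.
#' @param margin_ms Margin removed on each side of a blink.
#' @param max_blink_ms Longest missing run treated as a blink.
#' @return Numeric vector with blinks interpolated.  Valid samples outside
#'   margined spans are never modified.
#' @examples
#' x <- c(3, 3, 3, NA, NA, 3.5, 3.5, 3.5)
#' deblink(x, period_ms = 100)
#' @export
deblink <- function(x, period_ms, margin_ms = 100, max_blink_ms = 500) {
  x <- as.numeric(x)
  n <- length(x)
  if (n == 0L || !anyNA(x)) return(x)
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  blink <- r$values & (r$lengths * period_ms <= max_blink_ms + 1e-6)
  long_idx <- unlist(mapply(function(s, e, keep) if (keep) s:e,
                            starts, ends, r$values & !blink,
                            SIMPLIFY = FALSE), use.names = FALSE)
  if (!any(blink)) return(x)

  margin_n <- ceiling(margin_ms / period_ms)
  spans <- cbind(pmax(1L, starts[blink] - margin_n),
                 pmin(n, ends[blink] + margin_n))
  # merge overlapping / adjacent margined spans
  ord <- order(spans[, 1L])
  spans <- spans[ord, , drop = FALSE]
  merged <- spans[1L, , drop = FALSE]
  for (i in seq_len(nrow(spans))[-1L]) {
    if (spans[i, 1L] <= merged[nrow(merged), 2L] + 1L) {
      merged[nrow(merged), 2L] <- max(merged[nrow(merged), 2L], spans[i, 2L])
    } else {
      merged <- rbind(merged, spans[i, , drop = FALSE])
    }
  }

  out <- x
  for (i in seq_len(nrow(merged))) {
    s <- merged[i, 1L]; e <- merged[i, 2L]
    left <- if (s > 1L) x[s - 1L] else NA_real_
    right <- if (e < n) x[e + 1L] else NA_real_
    span_len <- e - s + 1L
    if (is.na(left) || is.na(right)) {
      out[s:e] <- NA_real_
    } else {
      out[s:e] <- left + (right - left) * seq_len(span_len) / (span_len + 1L)
    }
  }
  # runs longer than the blink threshold stay missing even when a margin of
  # a neighbouring blink was interpolated across them
  if (length(long_idx)) out[long_idx] <- NA_real_
  out
}

#' Baseline-corrected pupil dilation response for a trial
#'
#' The two (preprocessed) eyes are fused by averaging the available eyes at
#' each timestamp.  The baseline is the mean fused diameter in the 100 ms
#' before cue onset, and the pupil dilation response (PDR) is the mean fused
#' diameter in the 2-second epoch after onset minus the baseline.  The trial
#' is invalid when the baseline window holds no valid fused sample or when
#' more than half of the fused samples in the trace are missing.
#'
#' @param left,right Numeric vectors: preprocessed traces per eye (`NA` =
#'   missing), sampled at the same timestamps.
#' @param t_ms Timestamps (ms) of the samples.
#' @param cue_onset_ms Cue onset, in the same time base as `t_ms`.
#' @param baseline_ms Baseline window length before onset.
#' @param epoch_ms Epoch length after onset.
#' @param max_missing Invalidity threshold on the fused missing fraction.
#' @return A one-row tibble: `baseline_mm`, `pdr_mm`, `missing_frac`,
#'   `valid`.  `pdr_mm` is `NA` when invalid.
#' @examples
#' t <- seq(0, 8000 - 1, by = 1000 / 120)
#' epoch_pdr(rep(3, length(t)), rep(3, length(t)), t, cue_onset_ms = 4000)
#' @export
epoch_pdr <- function(left, right, t_ms, cue_onset_ms,
                      baseline_ms = 100, epoch_ms = 2000, max_missing = 0.5) {
  stopifnot(length(left) == length(right), length(left) == length(t_ms))
  if (cue_onset_ms - baseline_ms < t_ms[1L] ||
      cue_onset_ms >= t_ms[length(t_ms)]) {
    stop("cue onset outside the recorded pupil span", call. = FALSE)
  }
  out <- epoch_pdr_core(left, right, t_ms, cue_onset_ms, baseline_ms,
                        epoch_ms, max_missing)
  tibble::tibble(baseline_mm = out$baseline_mm, pdr_mm = out$pdr_mm,
                 missing_frac = out$missing_frac, valid = out$valid)
}

epoch_pdr_core <- function(left, right, t_ms, cue_onset_ms, baseline_ms,
                           epoch_ms, max_missing) {
  fused <- fuse_eyes(left, right)
  in_baseline <- t_ms >= cue_onset_ms - baseline_ms & t_ms < cue_onset_ms
  in_epoch <- t_ms >= cue_onset_ms & t_ms < cue_onset_ms + epoch_ms
  baseline_vals <- fused[in_baseline]
  missing_frac <- mean(is.na(fused))
  has_baseline <- any(!is.na(baseline_vals))
  valid <- has_baseline && missing_frac <= max_missing
  baseline <- if (has_baseline) mean(baseline_vals, na.rm = TRUE) else NA_real_
  pdr <- if (valid) mean(fused[in_epoch], na.rm = TRUE) - baseline else NA_real_
  list(baseline_mm = baseline, pdr_mm = pdr, missing_frac = missing_frac,
       valid = valid)
}

# per-timestamp mean of the available eyes
fuse_eyes <- function(left, right) {
  fused <- (left + right) / 2
  lo <- is.na(right) & !is.na(left)
  ro <- is.na(left) & !is.na(right)
  fused[lo] <- left[lo]
  fused[ro] <- right[ro]
  fused
}

#' Participant-level validity rule
#'
#' A participant is retained when at most half of their test trials are
#' invalid; strictly more than 50% invalid trials removes the participant.
#'
#' @param trial_valid A logical vector, one flag per test trial.
#' @return `TRUE` (keep) or `FALSE` (remove).
#' @examples
#' participant_validity(rep(c(TRUE, FALSE), c(28, 28)))  # exactly 50%: keep
#' @export
participant_validity <- function(trial_valid) {
  stopifnot(is.logical(trial_valid), length(trial_valid) > 0L)
  mean(!trial_valid) <= 0.5
}

#' Pupil metrics for every trial of a participant
#'
#' Runs the full per-eye preprocessing chain (median filter, blink
#' margining/interpolation) and the fusion/baseline/epoch stage for each
#' trial of a long pupil table.
#'
#' @param pupil A tibble with columns `trial`, `t_ms`, `left_mm`, `right_mm`
#'   (`NA` = missing sample).
#' @param cue_onset_ms Cue onset within each trial's time base (scalar or
#'   tibble with `trial`, `cue_onset_ms`).
#' @inheritParams epoch_pdr
#' @inheritParams median_smooth
#' @inheritParams deblink
#' @return A tibble, one row per trial: `trial`, `baseline_mm`, `pdr_mm`,
#'   `missing_frac`, `valid`.
#' @export
pupil_metrics <- function(pupil, cue_onset_ms = 4000, window = 11L,
                          margin_ms = 100, max_blink_ms = 500,
                          baseline_ms = 100, epoch_ms = 2000,
                          max_missing = 0.5) {
  stopifnot(all(c("trial", "t_ms", "left_mm", "right_mm") %in% names(pupil)))
  onsets <- if (is.data.frame(cue_onset_ms)) cue_onset_ms else NULL
  idx <- split(seq_len(nrow(pupil)), pupil$trial)
  trials <- as.integer(names(idx))
  rows <- lapply(seq_along(idx), function(i) {
    ii <- idx[[i]]
    t_ms <- pupil$t_ms[ii]
    onset <- if (is.null(onsets)) cue_onset_ms else
      onsets$cue_onset_ms[onsets$trial == trials[i]]
    period <- stream_period(t_ms)
    prep <- function(x) {
      deblink(median_smooth(x, window = window), period_ms = period,
              margin_ms = margin_ms, max_blink_ms = max_blink_ms)
    }
    epoch_pdr_core(prep(pupil$left_mm[ii]), prep(pupil$right_mm[ii]), t_ms,
                   onset, baseline_ms = baseline_ms, epoch_ms = epoch_ms,
                   max_missing = max_missing)
  })
  num <- function(f) vapply(rows, `[[`, numeric(1L), f)
  tibble::tibble(
    trial = trials,
    baseline_mm = num("baseline_mm"),
    pdr_mm = num("pdr_mm"),
    missing_frac = num("missing_frac"),
    valid = vapply(rows, `[[`, logical(1L), "valid")
  )
}
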