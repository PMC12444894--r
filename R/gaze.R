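#' Reconstruct short gaps in a gaze stream
#'
#' Eye-tracking streams label each sample with the gazed area of interest
#' (AOI): `"CUE"` (the floating ball), `"TABLET"` (the task screen),
#' `"OTHER"` (rest of the room) or `"MISSING"`.  Episodes of missing data of
#' 500 ms or less (typically blinks) are reconstructed by carrying the last
#' valid AOI label forward over the gap; longer episodes are left missing
#' and count as invalid data downstream.  A leading gap with no preceding
#' valid sample also remains missing.
#'
#' @param stream A tibble with columns `t_ms` (uniformly spaced, strictly
#'   increasing) and `target` (AOI label).
#' @param max_gap_ms Longest gap (run length times sample period) that is
#'   reconstructed; default 500 ms.
#' @return The stream with short `MISSING` runs relabelled.  Idempotent and
#'   never alters a non-missing sample.
#' @examples
#' s <- tibble::tibble(t_ms = seq(0, 990, by = 10),
#'                     target = rep(c("TABLET", "MISSING", "CUE"), c(40, 20, 40)))
#' table(reconstruct_gaps(s)$target)
#' @export
reconstruct_gaps <- function(stream, max_gap_ms = 500) {
  check_stream(stream)
  period <- stream_period(stream$t_ms)
  stream$target <- reconstruct_gaps_core(stream$target, period, max_gap_ms)
  stream
}

reconstruct_gaps_core <- function(target, period, max_gap_ms = 500) {
  r <- rle(target)
  for (i in seq_along(r$values)) {
    if (r$values[i] != "MISSING" || i == 1L) next
    if (r$lengths[i] * period <= max_gap_ms + 1e-6) r$values[i] <- r$values[i - 1L]
  }
  inverse.rle(r)
}

#' Detect fixations in a gaze stream
#'
#' A fixation is a maximal run of identical AOI labels lasting at least
#' `min_fix_ms` (100 ms by default).  Missing samples never produce
#' fixations.  No velocity or dispersion criterion is applied: in this
#' paradigm the AOI label and its duration define the fixation.
#'
#' @inheritParams reconstruct_gaps
#' @param min_fix_ms Minimum fixation duration (inclusive).
#' @return A tibble with columns `aoi`, `start_ms`, `end_ms`, `duration_ms`
#'   (run length times the sample period), one row per fixation event in
#'   temporal order.
#' @examples
#' s <- tibble::tibble(t_ms = seq(0, 1990, by = 1000 / 120)[1:240],
#'                     target = rep(c("CUE", "TABLET"), each = 120))
#' detect_fixations(s)
#' @export
detect_fixations <- function(stream, min_fix_ms = 100) {
  check_stream(stream)
  period <- stream_period(stream$t_ms)
  r <- rle(stream$target)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "MISSING" & r$lengths * period >= min_fix_ms - 1e-6
  tibble::tibble(
    aoi = r$values[keep],
    start_ms = stream$t_ms[starts[keep]],
    end_ms = stream$t_ms[ends[keep]] + period,
    duration_ms = r$lengths[keep] * period
  )
}

#' Per-trial attention metrics
#'
#' Dwell time is the summed duration of fixation events on an AOI divided by
#' the trial duration, expressed in milliseconds of dwell per second of
#' trial; the fixation rate is the number of cue fixation events per second.
#' A trial is invalid when more than half of its samples are still missing
#' after gap reconstruction (or when the stream is empty).
#'
#' @inheritParams detect_fixations
#' @param trial_duration_s Trial duration in seconds (> 0) used as the
#'   normalizer; defaults to the recorded stream span.
#' @param max_missing Invalidity threshold on the missing-sample fraction
#'   (strictly greater than; default 0.5).
#' @return A one-row tibble: `cue_dwell_ms_per_s`, `tablet_dwell_ms_per_s`,
#'   `cue_fixations_per_s`, `missing_frac`, `valid`.
#' @examples
#' s <- tibble::tibble(t_ms = seq(0, 16000 - 1, by = 1000 / 120),
#'                     target = rep(c("CUE", "TABLET"), c(480, 1440)))
#' attention_metrics(s, trial_duration_s = 16)
#' @export
attention_metrics <- function(stream, trial_duration_s = NULL,
                              min_fix_ms = 100, max_missing = 0.5) {
  check_stream(stream)
  if (nrow(stream) == 0L) {
    stop("empty gaze stream: trial has no samples", call. = FALSE)
  }
  period <- stream_period(stream$t_ms)
  if (is.null(trial_duration_s)) {
    trial_duration_s <- nrow(stream) * period / 1000
  }
  stopifnot(trial_duration_s > 0)
  out <- attention_metrics_core(stream$target, period, trial_duration_s,
                                min_fix_ms, max_missing)
  tibble::tibble(
    cue_dwell_ms_per_s = out$cue_dwell_ms_per_s,
    tablet_dwell_ms_per_s = out$tablet_dwell_ms_per_s,
    cue_fixations_per_s = out$cue_fixations_per_s,
    missing_frac = out$missing_frac,
    valid = out$valid
  )
}

attention_metrics_core <- function(target, period, trial_duration_s,
                                   min_fix_ms, max_missing) {
  r <- rle(target)
  keep <- r$values != "MISSING" & r$lengths * period >= min_fix_ms - 1e-6
  dur <- r$lengths * period
  missing_frac <- sum(r$lengths[r$values == "MISSING"]) / length(target)
  list(
    cue_dwell_ms_per_s =
      sum(dur[keep & r$values == "CUE"]) / trial_duration_s,
    tablet_dwell_ms_per_s =
      sum(dur[keep & r$values == "TABLET"]) / trial_duration_s,
    cue_fixations_per_s =
      sum(keep & r$values == "CUE") / trial_duration_s,
    missing_frac = missing_frac,
    valid = missing_frac <= max_missing
  )
}

#' Gaze metrics for every trial of a participant
#'
#' Convenience wrapper: reconstructs gaps and computes [attention_metrics()]
#' for each trial of a long gaze table.
#'
#' @param gaze A tibble with columns `trial`, `t_ms`, `target` as produced by
#'   [simulate_participant()] (or read from the documented CSV contract).
#' @param durations A tibble with columns `trial` and `duration_s` giving
#'   each trial's normalizing duration (for test trials, the cue-present
#'   span).
#' @inheritParams attention_metrics
#' @param max_gap_ms Passed to [reconstruct_gaps()].
#' @return A tibble with one row per trial: `trial` plus the
#'   [attention_metrics()] columns.
#' @export
gaze_metrics <- function(gaze, durations, min_fix_ms = 100, max_gap_ms = 500,
                         max_missing = 0.5) {
  stopifnot(all(c("trial", "t_ms", "target") %in% names(gaze)))
  idx <- split(seq_len(nrow(gaze)), gaze$trial)
  trials <- as.integer(names(idx))
  rows <- lapply(seq_along(idx), function(i) {
    ii <- idx[[i]]
    t_ms <- gaze$t_ms[ii]
    period <- stream_period(t_ms)
    dur <- durations$duration_s[durations$trial == trials[i]]
    if (length(dur) != 1L) dur <- length(ii) * period / 1000
    target <- reconstruct_gaps_core(gaze$target[ii], period, max_gap_ms)
    attention_metrics_core(target, period, dur, min_fix_ms, max_missing)
  })
  num <- function(f) vapply(rows, `[[`, numeric(1L), f)
  tibble::tibble(
    trial = trials,
    cue_dwell_ms_per_s = num("cue_dwell_ms_per_s"),
    tablet_dwell_ms_per_s = num("tablet_dwell_ms_per_s"),
    cue_fixations_per_s = num("cue_fixations_per_s"),
    missing_frac = num("missing_frac"),
    valid = vapply(rows, `[[`, logical(1L), "valid")
  )
}

check_stream <- function(stream) {
  stopifnot(is.data.frame(stream), all(c("t_ms", "target") %in% names(stream)))
  invisible(stream)
}

stream_period <- function(t_ms) {
  if (length(t_ms) < 2L) return(1000 / 120)
  d <- diff(t_ms[seq_len(min(length(t_ms), 50L))])
  stopifnot(all(d > 0))
  stats::median(d)
}
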