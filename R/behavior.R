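#' Clean 2-back reaction times
#'
#' Reaction-time cleaning for the whole test phase of one participant:
#' incorrect and late/omitted responses are removed first; then the
#' participant's mean and standard deviation of the remaining latencies are
#' computed once, pooled across all test trials, and any latency deviating
#' by 3 or more SDs from that mean is excluded.  The outlier pass is
#' single (non-iterative).  When the pooled SD is zero (all retained
#' latencies identical) nothing is removed.
#'
#' @param responses A tibble of one participant's 2-back responses with
#'   columns `correct` (logical), `rt_ms` (`NA` when no response was made
#'   within the response window).  Extra columns are preserved.
#' @param sd_cutoff Outlier threshold in pooled SD units (deviation `>=`
#'   cutoff times SD is removed).
#' @return The input with a logical `rt_retained` column: `TRUE` for
#'   responses that enter latency averages.
#' @examples
#' r <- tibble::tibble(correct = c(TRUE, TRUE, TRUE, FALSE),
#'                     rt_ms = c(500, 510, 1490, 480))
#' clean_rts(r)
#' @export
clean_rts <- function(responses, sd_cutoff = 3) {
  stopifnot(all(c("correct", "rt_ms") %in% names(responses)))
  eligible <- responses$correct & !is.na(responses$rt_ms)
  rts <- responses$rt_ms[eligible]
  if (length(rts) < 2L) {
    warning("fewer than 2 retained responses; latency metrics are degenerate",
            call. = FALSE)
    responses$rt_retained <- eligible
    return(responses)
  }
  m <- mean(rts)
  s <- stats::sd(rts)
  keep <- if (s > 0) abs(responses$rt_ms - m) < sd_cutoff * s else TRUE
  responses$rt_retained <- eligible & !is.na(responses$rt_ms) & keep
  responses
}

#' Score one trial's 2-back performance and threat ratings
#'
#' Only letter positions 3 onwards are scoreable (the first two letters have
#' no 2-back reference).  The error rate is
#' `1 - (hits + correct rejections) / scoreable letters`; omissions are
#' neither hits nor correct rejections and so count as errors.  Mean latency
#' is taken over the trial's retained correct responses (see [clean_rts()]).
#' Pain threat is the mean of the trial's pain-expectancy and pain-related
#' fear ratings (0-10 numerical rating scales).
#'
#' @param responses The trial's scoreable responses: tibble with `correct`,
#'   `rt_ms`, and (after [clean_rts()]) `rt_retained`.  Rows are the
#'   scoreable letters only.
#' @param expectancy,fear The trial's two threat ratings (0-10).
#' @return One-row tibble: `mean_rt_ms`, `error_rate`, `pain_threat`,
#'   `n_scoreable`.
#' @examples
#' r <- clean_rts(tibble::tibble(correct = rep(c(TRUE, FALSE), c(9, 1)),
#'                               rt_ms = c(rnorm(9, 550, 20), NA)))
#' score_trial(r, expectancy = 6, fear = 4)
#' @export
score_trial <- function(responses, expectancy, fear) {
  n <- nrow(responses)
  if (n == 0L) {
    stop("trial has no scoreable letters; metrics undefined", call. = FALSE)
  }
  if (!"rt_retained" %in% names(responses)) {
    responses <- clean_rts(responses)
  }
  retained <- responses$rt_retained & responses$correct
  tibble::tibble(
    mean_rt_ms = if (any(retained)) mean(responses$rt_ms[retained]) else NA_real_,
    error_rate = 1 - sum(responses$correct) / n,
    pain_threat = (expectancy + fear) / 2,
    n_scoreable = n
  )
}

#' Colour-discrimination accuracy
#'
#' Fraction of correct same/different judgements over the 42 trials of the
#' colour-discrimination phase.
#'
#' @param color_responses Tibble with logical columns `same_expected` and
#'   `responded_same` (or a logical `correct` column), no missing responses.
#' @return Accuracy in `[0, 1]`.
#' @examples
#' cp <- build_color_phase(seed = 1)
#' cp$responded_same <- cp$same_expected  # a perfect observer
#' color_accuracy(cp)
#' @export
color_accuracy <- function(color_responses) {
  if ("correct" %in% names(color_responses)) {
    correct <- color_responses$correct
  } else {
    stopifnot(all(c("same_expected", "responded_same") %in%
                    names(color_responses)))
    correct <- color_responses$same_expected == color_responses$responded_same
  }
  if (anyNA(correct)) stop("missing colour responses", call. = FALSE)
  mean(correct)
}

#' Practice-phase gate
#'
#' Participants proceed beyond the practice block only when 2-back accuracy
#' over its scoreable letters reaches at least 70% (inclusive); otherwise
#' the practice phase is repeated.
#'
#' @param correct Logical vector of scoreable practice responses.
#' @param threshold Accuracy threshold (default 0.70).
#' @return `TRUE` when the gate is passed.
#' @examples
#' practice_gate(rep(c(TRUE, FALSE), c(21, 9)))  # 70% exactly: pass
#' @export
practice_gate <- function(correct, threshold = 0.70) {
  stopifnot(is.logical(correct), length(correct) > 0L)
  mean(correct) >= threshold
}

#' Behaviour metrics for every trial of a participant
#'
#' Applies participant-level RT cleaning once (pooled over all test trials)
#' and scores each trial.
#'
#' @param behavior Tibble of scoreable responses with columns `trial`,
#'   `correct`, `rt_ms`.
#' @param ratings Tibble with columns `trial`, `expectancy`, `fear`.
#' @inheritParams clean_rts
#' @return Tibble, one row per trial: `trial`, `mean_rt_ms`, `error_rate`,
#'   `pain_threat`, `n_scoreable`.
#' @export
behavior_metrics <- function(behavior, ratings, sd_cutoff = 3) {
  stopifnot(all(c("trial", "correct", "rt_ms") %in% names(behavior)),
            all(c("trial", "expectancy", "fear") %in% names(ratings)))
  cleaned <- clean_rts(behavior, sd_cutoff = sd_cutoff)
  out <- cleaned |>
    dplyr::group_by(.data$trial) |>
    dplyr::summarise(
      mean_rt_ms = {
        keep <- .data$rt_retained & .data$correct
        if (any(keep)) mean(.data$rt_ms[keep]) else NA_real_
      },
      error_rate = 1 - sum(.data$correct) / dplyr::n(),
      n_scoreable = dplyr::n(),
      .groups = "drop"
    )
  out |>
    dplyr::left_join(ratings, by = "trial") |>
    dplyr::mutate(pain_threat = (.data$expectancy + .data$fear) / 2) |>
    dplyr::select("trial", "mean_rt_ms", "error_rate", "pain_threat",
                  "n_scoreable")
}
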