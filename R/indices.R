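#' Category means of per-trial metrics
#'
#' Averages every metric over the valid test trials of each conditioned-cue
#' category (`PAIN` = CS+, `AMBIGUOUS` = CSA, `NONPAIN` = CS-).  Trials are
#' pooled at the trial level regardless of the specific cue (with the full
#' design's equal counts per cue this coincides with per-cue-then-category
#' averaging; after exclusions the pooled form is used).  Booster and
#' acquisition trials never contribute.  A metric's mean is `NA` when a
#' category has no valid trial for it; reinforced CS+ trials do contribute
#' to the CS+ means.
#'
#' @param trial_metrics Tibble with one row per test trial: `trial` plus any
#'   of `cue_dwell_ms_per_s`, `tablet_dwell_ms_per_s`, `cue_fixations_per_s`,
#'   `pdr_mm`, `mean_rt_ms`, `error_rate`, `pain_threat`, and per-family
#'   validity flags `gaze_valid` / `pupil_valid` (missing flags are treated
#'   as all-valid for that family).
#' @param plan A `session_plan` (or its `trials` tibble) mapping `trial`
#'   (= `index`) to `phase` and `category`.
#' @return A tibble, one row per category present, with the per-metric
#'   means and `n_trials`.
#' @export
category_means <- function(trial_metrics, plan) {
  trials <- if (inherits(plan, "session_plan")) plan$trials else plan
  stopifnot(all(c("index", "phase", "category") %in% names(trials)))
  joined <- dplyr::inner_join(
    trial_metrics,
    dplyr::select(trials, trial = "index", "phase", "category"),
    by = "trial"
  )
  joined <- dplyr::filter(joined, .data$phase == "TEST")

  gaze_cols <- intersect(
    c("cue_dwell_ms_per_s", "tablet_dwell_ms_per_s", "cue_fixations_per_s"),
    names(joined))
  pupil_cols <- intersect("pdr_mm", names(joined))
  beh_cols <- intersect(c("mean_rt_ms", "error_rate", "pain_threat"),
                        names(joined))
  gv <- if ("gaze_valid" %in% names(joined)) joined$gaze_valid else TRUE
  pv <- if ("pupil_valid" %in% names(joined)) joined$pupil_valid else TRUE
  for (col in gaze_cols) joined[[col]][!gv] <- NA_real_
  for (col in pupil_cols) joined[[col]][!pv] <- NA_real_

  joined |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(c(gaze_cols, pupil_cols, beh_cols)),
                    ~ mean(.x, na.rm = TRUE)),
      n_trials = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                ~ ifelse(is.nan(.x), NA_real_, .x)))
}

#' The seven ambiguous-minus-safe bias indices
#'
#' Each index is the `AMBIGUOUS` (CSA) category mean minus the `NONPAIN`
#' (CS-) category mean:
#'
#' * `ab_cue_dwell`, `ab_cue_fix` - attention bias toward the ambiguous cue
#'   (cue-AOI dwell ms/s; cue fixations /s); positive = more attention to
#'   ambiguous cues,
#' * `ab_tablet_dwell` - tablet-AOI dwell difference; negative values mean
#'   attention was drawn away from the task by ambiguous cues,
#' * `ib_threat` - interpretation bias in rated pain threat (0-10 NRS),
#' * `ib_pdr` - interpretation bias in the 2-s epoch pupil dilation (mm),
#' * `ti_latency`, `ti_error` - task interference in 2-back mean latency
#'   (ms) and error rate.
#'
#' CS+ means are never used by the indices (they serve the manipulation
#' checks and omnibus tests only).
#'
#' @param cat_means Output of [category_means()].
#' @return A one-row tibble with the seven indices.  An index is `NA` when
#'   either of its category means is missing.
#' @export
bias_indices <- function(cat_means) {
  need <- c("AMBIGUOUS", "NONPAIN")
  if (!all(need %in% cat_means$category)) {
    stop("category means for AMBIGUOUS and NONPAIN are required",
         call. = FALSE)
  }
  a <- cat_means[cat_means$category == "AMBIGUOUS", ]
  s <- cat_means[cat_means$category == "NONPAIN", ]
  d <- function(col) {
    if (!col %in% names(cat_means)) return(NA_real_)
    a[[col]] - s[[col]]
  }
  tibble::tibble(
    ab_cue_dwell = d("cue_dwell_ms_per_s"),
    ab_tablet_dwell = d("tablet_dwell_ms_per_s"),
    ab_cue_fix = d("cue_fixations_per_s"),
    ib_threat = d("pain_threat"),
    ib_pdr = d("pdr_mm"),
    ti_latency = d("mean_rt_ms"),
    ti_error = d("error_rate")
  )
}

#' Post-acquisition manipulation-check means
#'
#' After the acquisition phase every conditioned cue is rated once more.
#' This returns each participant's mean post-acquisition expectancy (and
#' fear) over the two CS+ cues and over the two CS- cues, the paired inputs
#' of the acquisition manipulation check.
#'
#' @param postacq Tibble with columns `cue_id`, `category`, `expectancy`,
#'   `fear` (one row per conditioned cue).
#' @return One-row tibble: `csplus_expectancy`, `csminus_expectancy`,
#'   `csplus_fear`, `csminus_fear`.
#' @export
acquisition_check <- function(postacq) {
  stopifnot(all(c("category", "expectancy", "fear") %in% names(postacq)))
  if (anyNA(postacq$expectancy) || anyNA(postacq$fear)) {
    stop("missing post-acquisition rating; participant flagged", call. = FALSE)
  }
  pl <- postacq$category == "PAIN"
  mn <- postacq$category == "NONPAIN"
  if (!any(pl) || !any(mn)) {
    stop("post-acquisition ratings must cover both conditioned categories",
         call. = FALSE)
  }
  tibble::tibble(
    csplus_expectancy = mean(postacq$expectancy[pl]),
    csminus_expectancy = mean(postacq$expectancy[mn]),
    csplus_fear = mean(postacq$fear[pl]),
    csminus_fear = mean(postacq$fear[mn])
  )
}
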