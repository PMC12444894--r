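#' Generalization gradient of threat ratings across the cue continuum
#'
#' Mean rated pain threat per gradient position over the test phase, the
#' classic fear-generalization gradient: high at the conditioned pain end,
#' decaying across the ambiguous middle to the safety end.
#'
#' @param cohort A `cohort` (list of `participant_record`s).
#' @return A ggplot object.
#' @export
plot_generalization <- function(cohort) {
  df <- purrr::map_dfr(cohort, function(rec) {
    trials <- dplyr::filter(rec$session$trials, .data$phase == "TEST")
    rec$ratings |>
      dplyr::inner_join(dplyr::select(trials, trial = "index",
                                      "gradient_pos", "category"),
                        by = "trial") |>
      dplyr::mutate(id = rec$id,
                    pain_threat = (.data$expectancy + .data$fear) / 2)
  })
  summ <- df |>
    dplyr::group_by(.data$id, .data$gradient_pos, .data$category) |>
    dplyr::summarise(pain_threat = mean(.data$pain_threat),
                     .groups = "drop") |>
    dplyr::group_by(.data$gradient_pos, .data$category) |>
    dplyr::summarise(mean = mean(.data$pain_threat),
                     se = stats::sd(.data$pain_threat) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$gradient_pos, y = .data$mean,
                                     colour = .data$category)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey40") +
    ggplot2::scale_x_continuous(breaks = 1:7) +
    ggplot2::labs(x = "Gradient position (1 = lightest shade)",
                  y = "Mean pain threat (0-10)",
                  colour = "Cue category",
                  title = "Threat generalization across the cue gradient") +
    ggplot2::theme_minimal()
}

#' Distribution of the seven bias indices across a cohort
#'
#' @param object A tibble from [cohort_indices()].
#' @param ... Unused.
#' @return A ggplot object (one violin/box panel per index; indices are on
#'   very different scales, so panels have free y axes).
#' @export
plot_indices <- function(object, ...) {
  df <- object |>
    dplyr::filter(.data$valid, !.data$chronic_pain) |>
    dplyr::select(dplyr::all_of(c("id", index_names()))) |>
    tidyr::pivot_longer(-"id", names_to = "index")
  ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$value)) +
    ggplot2::geom_violin(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Index value (ambiguous minus safe)",
                  title = "Cohort bias and interference indices") +
    ggplot2::theme_minimal()
}

#' Preprocessed pupil trace of one trial
#'
#' Shows the raw and preprocessed fused pupil trace with the baseline
#' window and the 2-s dilation epoch marked.
#'
#' @param record A `participant_record`.
#' @param trial Trial index (a test trial).
#' @param config A [pipeline_config()].
#' @return A ggplot object.
#' @export
plot_trial_pupil <- function(record, trial, config = pipeline_config()) {
  df <- dplyr::filter(record$pupil, .data$trial == !!trial)
  if (nrow(df) == 0L) stop("no pupil data for that trial", call. = FALSE)
  period <- stream_period(df$t_ms)
  prep <- function(x) {
    deblink(median_smooth(x, window = config$median_window),
            period_ms = period, margin_ms = config$blink_margin_ms,
            max_blink_ms = config$max_blink_ms)
  }
  fused_raw <- rowMeans(cbind(df$left_mm, df$right_mm), na.rm = TRUE)
  fused <- rowMeans(cbind(prep(df$left_mm), prep(df$right_mm)), na.rm = TRUE)
  long <- tibble::tibble(
    t_s = rep(df$t_ms, 2L) / 1000,
    pupil_mm = c(ifelse(is.nan(fused_raw), NA, fused_raw),
                 ifelse(is.nan(fused), NA, fused)),
    stage = rep(c("raw", "preprocessed"), each = nrow(df))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_s, y = .data$pupil_mm,
                                     colour = .data$stage)) +
    ggplot2::annotate("rect", xmin = 3.9, xmax = 4, ymin = -Inf, ymax = Inf,
                      alpha = 0.3, fill = "orange") +
    ggplot2::annotate("rect", xmin = 4, xmax = 6, ymin = -Inf, ymax = Inf,
                      alpha = 0.15, fill = "red") +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::labs(x = "Time (s)", y = "Pupil diameter (mm)",
                  colour = NULL,
                  title = sprintf("Trial %d pupil trace (baseline and epoch shaded)",
                                  trial)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_indices
#' @importFrom ggplot2 autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.cohort_analysis <- function(object, ...) {
  plot_indices(object$data, ...)
}
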