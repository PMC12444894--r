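#' Pipeline configuration
#'
#' All constants of the preprocessing and analysis pathway in one place,
#' overridable individually: fixation threshold 100 ms, reconstructable gap
#' 500 ms, pupil median-filter window 11 samples, blink margin 100 ms and
#' blink ceiling 500 ms, pupil baseline window 100 ms before cue onset,
#' dilation epoch 2000 ms, trial/participant validity cutoffs at 50%
#' missing/invalid, reaction-time outlier cutoff 3 SD, and the 1500-ms
#' response window; plus the simulation block (`n`, `seed`, the generative
#' [participant_params()] and [cohort_params()]).  The configuration is
#' echoed into every pipeline report for provenance.
#'
#' @param n Cohort size for simulation.
#' @param seed Master seed.
#' @param params,between Generative parameter objects.
#' @param ... Named overrides of the preprocessing constants listed above.
#' @return An object of class `pipeline_config` (a named list).
#' @examples
#' pipeline_config(n = 10, seed = 3, min_fix_ms = 80)$min_fix_ms
#' @export
pipeline_config <- function(n = 85L, seed = 1L,
                            params = participant_params(),
                            between = cohort_params(), ...) {
  cfg <- list(
    n = n, seed = seed, params = params, between = between,
    min_fix_ms = 100, max_gap_ms = 500,
    median_window = 11L, blink_margin_ms = 100, max_blink_ms = 500,
    baseline_ms = 100, epoch_ms = 2000,
    max_missing = 0.5, rt_sd_cutoff = 3, response_window_ms = 1500
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Run the full simulate-preprocess-analyze pipeline
#'
#' Simulates (or accepts) a cohort, derives every participant's trial
#' metrics and bias indices, runs the statistical battery, and optionally
#' writes the intermediate tables, a JSON results bundle and a stage log to
#' `out_dir`.  The run is deterministic under a fixed configuration seed.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optionally, an already-simulated `cohort` (skips the
#'   simulation stage).
#' @param out_dir Optional output directory (created if needed).
#' @return A list of class `pipeline_result`: `config`, `indices` (the
#'   per-participant table), `analysis` (a `cohort_analysis`), and `log`
#'   (tibble of stage messages and record counts, including the exclusion
#'   audit: input n always equals analyzed n plus the sum of exclusions).
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         out_dir = NULL) {
  log <- list()
  note <- function(stage, message, count = NA_integer_) {
    log[[length(log) + 1L]] <<- tibble::tibble(
      stage = stage, message = message, count = as.integer(count))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  if (is.null(cohort)) {
    cohort <- run_stage("simulate", simulate_cohort(
      config$n, params = config$params, between = config$between,
      seed = config$seed))
    note("simulate", "participants simulated", length(cohort))
  } else {
    note("simulate", "pre-supplied cohort", length(cohort))
  }

  indices <- run_stage("indices", cohort_indices(cohort, config = config))
  note("indices", "participants with derived indices", nrow(indices))
  if (all(!indices$valid)) {
    stop("pipeline stage 'indices' produced an empty cohort: ",
         "every participant failed the validity rule", call. = FALSE)
  }
  analysis <- run_stage("stats", analyze_cohort(indices))
  note("stats", "participants analyzed", analysis$exclusions$n_analyzed)
  note("stats", "excluded: chronic pain", analysis$exclusions$chronic_pain)
  note("stats", "excluded: invalid data", analysis$exclusions$invalid_data)
  note("stats", "excluded: incomplete indices",
       analysis$exclusions$incomplete_indices)

  result <- structure(
    list(config = config, indices = indices, analysis = analysis,
         log = dplyr::bind_rows(log)),
    class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(indices, file.path(out_dir, "indices.csv"))
    readr::write_csv(result$log, file.path(out_dir, "log.csv"))
    write_session_csv(cohort[[1L]]$session,
                      file.path(out_dir, "example_session.csv"))
    jsonlite::write_json(
      pipeline_report(result), file.path(out_dir, "results.json"),
      auto_unbox = TRUE, digits = NA, na = "null")
    note("write", paste("artifacts written to", out_dir))
    result$log <- dplyr::bind_rows(log)
  }
  result
}

# flat, JSON-friendly summary of a pipeline result (config echoed for
# provenance)
pipeline_report <- function(result) {
  a <- result$analysis
  cfg <- result$config
  list(
    config = list(
      n = cfg$n, seed = cfg$seed,
      constants = cfg[c("min_fix_ms", "max_gap_ms", "median_window",
                        "blink_margin_ms", "max_blink_ms", "baseline_ms",
                        "epoch_ms", "max_missing", "rt_sd_cutoff",
                        "response_window_ms")],
      params = unclass(cfg$params), between = unclass(cfg$between),
      sex_coding = "0 = female, 1 = male"),
    exclusions = as.list(a$exclusions),
    manipulation = list(
      acquisition_t = a$manipulation$acquisition$t,
      acquisition_df = a$manipulation$acquisition$df,
      acquisition_dz = a$manipulation$acquisition$d_z,
      color_accuracy_mean = a$manipulation$color_accuracy_mean),
    index_means = as.list(colMeans(a$data[index_names()])),
    index_sds = as.list(vapply(a$data[index_names()], stats::sd,
                               numeric(1L))),
    threat_anova = a$anovas$pain_threat$omnibus[
      c("F", "df1_gg", "df2_gg", "p", "partial_eta2")],
    correlations = a$correlations,
    regressions = purrr::map(result$analysis$regressions, "steps")
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$analysis)
  invisible(x)
}

#' Write / read per-participant raw streams
#'
#' Plain-CSV writers for the documented raw-data contract (one file per
#' stream: gaze, pupil, behaviour, ratings), with timestamps in integer
#' milliseconds and missing values as empty fields, plus a cohort manifest.
#'
#' @param record A `participant_record`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_participant_csv <- function(record, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(record$gaze, file.path(dir, "gaze.csv"))
  readr::write_csv(record$pupil, file.path(dir, "pupil.csv"))
  readr::write_csv(record$behavior, file.path(dir, "behavior.csv"))
  readr::write_csv(record$ratings, file.path(dir, "ratings.csv"))
  readr::write_csv(record$postacq, file.path(dir, "postacq.csv"))
  readr::write_csv(record$color, file.path(dir, "color.csv"))
  write_session_csv(record$session, file.path(dir, "session.csv"))
  jsonlite::write_json(
    list(id = record$id, age = record$age, sex = record$sex,
         chronic_pain = record$chronic_pain,
         calibrated_mA = record$calibrated_mA,
         practice_attempts = record$practice_attempts),
    file.path(dir, "participant.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_participant_csv
#' @param cohort A `cohort`.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort) {
    write_participant_csv(rec, file.path(dir, sprintf("p%03d", rec$id)))
  }
  jsonlite::write_json(
    list(n = length(cohort), seed = attr(cohort, "seed"),
         participants = sprintf("p%03d", vapply(cohort, `[[`, integer(1L),
                                                "id"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
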