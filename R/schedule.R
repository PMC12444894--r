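#' Build the seven-cue colour gradient
#'
#' The paradigm uses seven balls whose colour runs along a single blue
#' gradient.  The two cues at one end are conditioned pain cues (`PAIN`,
#' "CS+"), the two at the other end are safety cues (`NONPAIN`, "CS-"), and
#' the three intermediate shades are ambiguous cues (`AMBIGUOUS`, "CSA") that
#' are perceptually equidistant between the conditioned ends and are never
#' reinforced.
#'
#' @param counterbalance Logical.  Under the default (`FALSE`) the lightest
#'   shades (gradient positions 1-2) are the pain cues; with `TRUE` the
#'   pain/non-pain ends of the gradient are exchanged.  The ambiguous middle
#'   (positions 3-5) is unaffected.
#'
#' @return A tibble with one row per cue and columns `cue_id` (`"CS1"` ...
#'   `"CS7"`), `gradient_pos` (1 = lightest shade), and `category`
#'   (`"PAIN"`, `"AMBIGUOUS"`, `"NONPAIN"`).
#' @examples
#' build_cues()
#' build_cues(counterbalance = TRUE)
#' @export
build_cues <- function(counterbalance = FALSE) {
  stopifnot(is.logical(counterbalance), length(counterbalance) == 1L)
  category <- if (counterbalance) {
    c("NONPAIN", "NONPAIN", "AMBIGUOUS", "AMBIGUOUS", "AMBIGUOUS", "PAIN", "PAIN")
  } else {
    c("PAIN", "PAIN", "AMBIGUOUS", "AMBIGUOUS", "AMBIGUOUS", "NONPAIN", "NONPAIN")
  }
  tibble::tibble(
    cue_id = paste0("CS", 1:7),
    gradient_pos = 1:7,
    category = category
  )
}

#' Ball trajectory set
#'
#' Eight trajectories of distinct duration, from 16 to 58 seconds in
#' 6-second steps (trajectory `k` lasts `16 + 6 * (k - 1)` seconds).  All
#' trajectories share onset and offset locations; only their durations
#' matter for the analysis.
#'
#' @return A tibble with columns `trajectory_id` (1-8) and `duration_s`.
#' @examples
#' trajectory_set()
#' @export
trajectory_set <- function() {
  tibble::tibble(trajectory_id = 1:8, duration_s = 16 + 6 * (0:7))
}

# Letters are presented every 2 s (500 ms letter + 1500 ms blank); in test
# trials the 2-back task starts 4 s before cue onset and runs to trial end.
n_letters_for_duration <- function(duration_s, cue_onset_ms = 4000) {
  as.integer(floor((duration_s + cue_onset_ms / 1000) / 2))
}

#' Build a full session plan
#'
#' Deterministically (given `seed`) constructs the complete trial schedule of
#' the paradigm:
#'
#' * a practice block (32 letters of 2-back, no cue),
#' * an acquisition phase of 8 trials (each conditioned cue CS1/CS2 and
#'   CS6/CS7 presented twice; pain cues reinforced on 100% of trials),
#' * a booster of 1 reinforced pain trial followed by 1 safety trial,
#' * a test phase of 56 pseudo-randomized trials in which every one of the
#'   7 cues appears once with each of the 8 trajectories; pain cues are
#'   reinforced at 50% (8 of 16 CS+ trials, 4 per CS+ cue) with exactly
#'   2 reinforced trials in every consecutive block of 14 trials,
#' * a colour-discrimination phase of all 21 unordered cue pairs plus 21
#'   self-pair fillers (each cue against itself 3 times), shuffled.
#'
#' Pseudo-randomization is rejection sampling: candidate test orders are
#' drawn until (a) a reinforcement assignment with 2 pain deliveries per
#' 14-trial block and 4 per CS+ cue exists and (b) no cue appears on two
#' consecutive trials (an added spacing convention).
#'
#' @param seed Integer seed; identical seeds yield identical plans.
#' @param counterbalance Passed to [build_cues()].
#' @param max_attempts Bound on rejection-sampling attempts before a
#'   schedule-constraint error is signalled.
#'
#' @return An object of class `session_plan`: a list with elements `seed`,
#'   `counterbalance`, `cues`, `trials` (tibble: `phase`, `index`, `cue_id`,
#'   `gradient_pos`, `category`, `trajectory_id`, `duration_s`, `reinforced`,
#'   `n_letters`, `cue_onset_ms`) and `color_pairs` (see
#'   [build_color_phase()]).
#' @examples
#' plan <- build_session(seed = 1)
#' dplyr::count(plan$trials, phase)
#' @export
build_session <- function(seed, counterbalance = FALSE, max_attempts = 1000L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  cues <- build_cues(counterbalance)
  traj <- trajectory_set()
  withr::with_seed(as.integer(seed), {
    acq <- build_acquisition(cues, traj)
    boost <- build_booster(cues, traj)
    test <- build_test_phase(cues, traj, max_attempts = max_attempts)
    color_pairs <- build_color_phase(seed = NULL, cues = cues)
  })

  practice <- tibble::tibble(
    phase = "PRACTICE", cue_id = NA_character_, gradient_pos = NA_integer_,
    category = NA_character_, trajectory_id = NA_integer_,
    duration_s = NA_real_, reinforced = FALSE, n_letters = 32L,
    cue_onset_ms = NA_real_
  )

  trials <- dplyr::bind_rows(practice, acq, boost, test)
  trials <- dplyr::mutate(trials, index = dplyr::row_number(), .after = "phase")

  structure(
    list(seed = as.integer(seed), counterbalance = counterbalance,
         cues = cues, trials = trials, color_pairs = color_pairs),
    class = "session_plan"
  )
}

# Acquisition: the four conditioned cues each twice; four randomly chosen
# trajectories go to the CS+ cues, the other four to the CS- cues.
build_acquisition <- function(cues, traj) {
  cond <- dplyr::filter(cues, .data$category %in% c("PAIN", "NONPAIN"))
  pain_cues <- cond$cue_id[cond$category == "PAIN"]
  safe_cues <- cond$cue_id[cond$category == "NONPAIN"]
  traj_ids <- sample(traj$trajectory_id)
  df <- tibble::tibble(
    cue_id = c(rep(pain_cues, each = 2L), rep(safe_cues, each = 2L)),
    trajectory_id = traj_ids
  )
  df <- df[sample(nrow(df)), ]
  df <- dplyr::left_join(df, cues, by = "cue_id")
  df <- dplyr::left_join(df, traj, by = "trajectory_id")
  tibble::tibble(
    phase = "ACQUISITION",
    cue_id = df$cue_id, gradient_pos = df$gradient_pos,
    category = df$category, trajectory_id = df$trajectory_id,
    duration_s = df$duration_s,
    reinforced = df$category == "PAIN",
    # no concurrent 2-back during acquisition; participants only watch and rate
    n_letters = 0L,
    cue_onset_ms = 0
  )
}

# Booster: one reinforced CS+ then one CS-, cue and trajectory drawn at
# random; flagged BOOSTER and excluded from all downstream metrics.
build_booster <- function(cues, traj) {
  pain_cue <- sample(cues$cue_id[cues$category == "PAIN"], 1L)
  safe_cue <- sample(cues$cue_id[cues$category == "NONPAIN"], 1L)
  df <- dplyr::left_join(
    tibble::tibble(cue_id = c(pain_cue, safe_cue),
                   trajectory_id = sample(traj$trajectory_id, 2L)),
    cues, by = "cue_id"
  )
  df <- dplyr::left_join(df, traj, by = "trajectory_id")
  tibble::tibble(
    phase = "BOOSTER",
    cue_id = df$cue_id, gradient_pos = df$gradient_pos,
    category = df$category, trajectory_id = df$trajectory_id,
    duration_s = df$duration_s,
    reinforced = c(TRUE, FALSE),
    n_letters = n_letters_for_duration(df$duration_s),
    cue_onset_ms = 4000
  )
}

build_test_phase <- function(cues, traj, max_attempts = 1000L) {
  grid <- tidyr::expand_grid(cue_id = cues$cue_id,
                             trajectory_id = traj$trajectory_id)
  pain_cues <- cues$cue_id[cues$category == "PAIN"]
  for (attempt in seq_len(max_attempts)) {
    perm <- repair_adjacent(grid$cue_id, sample(nrow(grid)))
    if (is.null(perm)) next
    ord <- grid[perm, ]
    reinforced <- assign_reinforcement(ord$cue_id, pain_cues,
                                       block_size = 14L, per_block = 2L,
                                       per_cue = 4L)
    if (is.null(reinforced)) next
    df <- dplyr::left_join(ord, cues, by = "cue_id")
    df <- dplyr::left_join(df, traj, by = "trajectory_id")
    return(tibble::tibble(
      phase = "TEST",
      cue_id = df$cue_id, gradient_pos = df$gradient_pos,
      category = df$category, trajectory_id = df$trajectory_id,
      duration_s = df$duration_s,
      reinforced = reinforced,
      n_letters = n_letters_for_duration(df$duration_s),
      cue_onset_ms = 4000
    ))
  }
  stop("schedule constraint could not be satisfied within ", max_attempts,
       " resampling attempts", call. = FALSE)
}

# Shuffle with local repair: starting from a random permutation of the
# trial rows, adjacent same-cue pairs are broken by swapping the offending
# trial with a random position where neither side ends up adjacent to its
# own cue.  Returns the repaired permutation, or NULL when repair stalls
# (the caller reshuffles).
repair_adjacent <- function(cue_ids, perm, max_passes = 50L) {
  n <- length(perm)
  for (pass in seq_len(max_passes)) {
    cues <- cue_ids[perm]
    bad <- which(cues[-1] == cues[-n]) + 1L
    if (length(bad) == 0L) return(perm)
    i <- bad[1L]
    ok <- FALSE
    for (j in sample(n)) {
      if (abs(j - i) <= 1L) next
      ci <- cues[i]; cj <- cues[j]
      if (ci == cj) next
      # neighbours after swapping positions i and j
      nb <- function(pos, val) {
        (pos > 1L && cues[pos - 1L] == val && pos - 1L != i && pos - 1L != j) ||
          (pos < n && cues[pos + 1L] == val && pos + 1L != i && pos + 1L != j)
      }
      if (nb(i, cj) || nb(j, ci)) next
      perm[c(i, j)] <- perm[c(j, i)]
      ok <- TRUE
      break
    }
    if (!ok) return(NULL)
  }
  NULL
}

# Choose reinforced trials: `per_block` per consecutive block among the CS+
# trials of that block, subject to `per_cue` reinforcements per CS+ cue
# overall.  Inner rejection loop; NULL when the drawn order admits no
# assignment within the attempt bound.
assign_reinforcement <- function(cue_seq, pain_cues, block_size, per_block,
                                 per_cue, inner_attempts = 200L) {
  n <- length(cue_seq)
  blocks <- split(seq_len(n), ceiling(seq_len(n) / block_size))
  for (a in seq_len(inner_attempts)) {
    chosen <- unlist(lapply(blocks, function(idx) {
      cs <- idx[cue_seq[idx] %in% pain_cues]
      if (length(cs) < per_block) return(NULL)
      sample(cs, per_block)
    }), use.names = FALSE)
    if (length(chosen) != per_block * length(blocks)) return(NULL)
    counts <- table(factor(cue_seq[chosen], levels = pain_cues))
    if (all(counts == per_cue)) {
      out <- rep(FALSE, n)
      out[chosen] <- TRUE
      return(out)
    }
  }
  NULL
}

#' Build the colour-discrimination phase
#'
#' Every unordered pair of distinct cues appears once (21 trials for 7 cues)
#' and, to balance button-press expectations, each cue is also paired with
#' itself 3 times (21 filler trials), for 42 trials in total, shuffled.
#'
#' @param seed Integer seed for the shuffle, or `NULL` to use the current RNG
#'   state (as [build_session()] does internally).
#' @param cues Cue tibble from [build_cues()]; any number of cues >= 2 is
#'   accepted (always 3 self-pairs per cue).
#' @return A tibble with columns `index`, `cue_a`, `cue_b`, `same_expected`.
#' @examples
#' build_color_phase(seed = 1)
#' @export
build_color_phase <- function(seed = NULL, cues = build_cues()) {
  k <- nrow(cues)
  stopifnot(k >= 2L)
  pairs <- utils::combn(cues$cue_id, 2L)
  distinct <- tibble::tibble(cue_a = pairs[1, ], cue_b = pairs[2, ],
                             same_expected = FALSE)
  self <- tibble::tibble(cue_a = rep(cues$cue_id, each = 3L),
                         cue_b = rep(cues$cue_id, each = 3L),
                         same_expected = TRUE)
  all_pairs <- dplyr::bind_rows(distinct, self)
  shuffle <- function() all_pairs[sample(nrow(all_pairs)), ]
  out <- if (is.null(seed)) shuffle() else withr::with_seed(as.integer(seed), shuffle())
  dplyr::mutate(out, index = dplyr::row_number(), .before = 1L)
}

#' @export
print.session_plan <- function(x, ...) {
  counts <- table(x$trials$phase)
  cat("<session_plan> seed", x$seed,
      if (x$counterbalance) "(counterbalanced gradient)" else "", "\n")
  cat("  trials:", paste(names(counts), counts, sep = "=", collapse = ", "), "\n")
  cat("  reinforced test trials:",
      sum(x$trials$reinforced[x$trials$phase == "TEST"]), "of",
      sum(x$trials$phase == "TEST"), "\n")
  cat("  colour trials:", nrow(x$color_pairs), "\n")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.session_plan <- function(x, ...) x$trials

#' Write / read a session plan
#'
#' The trial table is written as plain CSV (one row per trial) and the whole
#' plan, including the colour phase, as JSON.
#'
#' @param plan A `session_plan`.
#' @param path Output file path.
#' @return `path`, invisibly (writers); a `session_plan`-shaped list
#'   (`read_session_json()`).
#' @export
write_session_csv <- function(plan, path) {
  readr::write_csv(plan$trials, path)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
write_session_json <- function(plan, path) {
  jsonlite::write_json(
    list(seed = plan$seed, counterbalance = plan$counterbalance,
         cues = plan$cues, trials = plan$trials,
         color_pairs = plan$color_pairs),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(seed = x$seed, counterbalance = x$counterbalance,
         cues = tibble::as_tibble(x$cues),
         trials = tibble::as_tibble(x$trials),
         color_pairs = tibble::as_tibble(x$color_pairs)),
    class = "session_plan"
  )
}
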