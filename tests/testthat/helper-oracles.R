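# Brute-force reference implementations, kept deliberately naive and
# independent of the package's code paths.

# all maximal same-AOI runs of duration >= min_ms, by explicit scanning
slow_fixations <- function(target, t_ms, period, min_ms = 100) {
  n <- length(target)
  out <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && target[j + 1L] == target[i]) j <- j + 1L
    if (target[i] != "MISSING" && (j - i + 1L) * period >= min_ms - 1e-6) {
      out[[length(out) + 1L]] <- data.frame(
        aoi = target[i], start_ms = t_ms[i], end_ms = t_ms[j] + period,
        duration_ms = (j - i + 1L) * period)
    }
    i <- j + 1L
  }
  if (length(out) == 0L) {
    return(data.frame(aoi = character(), start_ms = numeric(),
                      end_ms = numeric(), duration_ms = numeric()))
  }
  do.call(rbind, out)
}

# per-position sort-based running median ignoring NAs, NA centres stay NA
slow_median <- function(x, window) {
  h <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    if (is.na(x[i])) return(NA_real_)
    w <- x[max(1L, i - h):min(n, i + h)]
    stats::median(w[!is.na(w)])
  }, numeric(1L))
}

# signed-rank Z with null mean/variance obtained by exhaustive enumeration
# of all 2^n sign assignments over the observed (possibly tied) ranks
slow_signed_rank_z <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  (w - mean(w_all)) / sqrt(mean(w_all^2) - mean(w_all)^2)
}

# random gaze stream generator for property tests
random_stream <- function(n, period, p_missing = 0.2) {
  tibble::tibble(
    t_ms = (seq_len(n) - 1L) * period,
    target = sample(c("CUE", "TABLET", "OTHER", "MISSING"), n,
                    replace = TRUE,
                    prob = c(0.2, 0.4, 0.2, p_missing))
  )
}

# fast participant parameter set used where stream content is incidental
fast_params <- function(...) {
  participant_params(sample_rate_hz = 60, ...)
}

null_effect_params <- function(...) {
  participant_params(
    sample_rate_hz = 60,
    ab_effect = c(PAIN = 0, AMBIGUOUS = 0, NONPAIN = 0),
    search_effect = c(PAIN = 0, AMBIGUOUS = 0, NONPAIN = 0),
    ib_threat_effect = 0, csplus_threat_effect = 0,
    pdr_effect_mm = c(PAIN = 0, AMBIGUOUS = 0, NONPAIN = 0),
    rt_slowing_ms = c(PAIN = 0, AMBIGUOUS = 0, NONPAIN = 0),
    error_effect = c(PAIN = 0, AMBIGUOUS = 0, NONPAIN = 0),
    ...
  )
}
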