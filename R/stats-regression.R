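#' Three-step hierarchical moderated regression
#'
#' Nested least-squares models for one task-interference outcome:
#'
#' 1. demographics only (`age`, `sex`),
#' 2. plus the attention-bias and interpretation-bias indices,
#' 3. plus their interaction, formed from mean-centered indices.
#'
#' Continuous predictors are centered before the interaction term is built.
#' Step increments are assessed with
#' `dF = (dR2 / dk) / ((1 - R2_full) / (n - k_full - 1))`, the standard
#' nested-model F (equal to [stats::anova()] on the consecutive fits).
#' Standardized coefficients come from refitting each step on fully
#' z-scored variables (binary sex, coded 0 = female / 1 = male, is
#' standardized like the rest for beta reporting).
#'
#' @param data A data frame with no missing values in the used columns.
#' @param outcome,ab,ib Column names (strings) of the outcome, the
#'   attention-bias index and the interpretation-bias index.
#' @param age,sex Column names of the demographic covariates.
#' @return An object of class `hier_reg`: list with `steps` (tibble: `step`,
#'   `r2`, `delta_r2`, `delta_f`, `df1`, `df2`, `p`), `coefs` (tibble per
#'   step and term: `estimate`, `beta`, `t`, `p`), the three `fits` (on
#'   centered predictors), and bookkeeping (`n`, column names).
#' @examples
#' d <- tibble::tibble(y = rnorm(60), age = rnorm(60, 21, 3),
#'                     sex = rbinom(60, 1, 0.2), ab = rnorm(60),
#'                     ib = rnorm(60))
#' hierarchical_regression(d, "y", "ab", "ib")
#' @export
hierarchical_regression <- function(data, outcome, ab, ib,
                                    age = "age", sex = "sex") {
  cols <- c(outcome, age, sex, ab, ib)
  stopifnot(all(cols %in% names(data)))
  d <- as.data.frame(data)[cols]
  if (anyNA(d)) stop("missing values in regression variables", call. = FALSE)
  names(d) <- c(".y", ".age", ".sex", ".ab", ".ib")
  n <- nrow(d)
  if (n <= 6L) stop("too few observations for the three-step model",
                    call. = FALSE)
  d$.age_c <- d$.age - mean(d$.age)
  d$.ab_c <- d$.ab - mean(d$.ab)
  d$.ib_c <- d$.ib - mean(d$.ib)
  d$.abib <- d$.ab_c * d$.ib_c

  f1 <- stats::lm(.y ~ .age_c + .sex, data = d)
  f2 <- stats::lm(.y ~ .age_c + .sex + .ab_c + .ib_c, data = d)
  f3 <- stats::lm(.y ~ .age_c + .sex + .ab_c + .ib_c + .abib, data = d)
  fits <- list(f1, f2, f3)
  if (any(vapply(fits, function(f) anyNA(stats::coef(f)), logical(1L)))) {
    stop("rank-deficient design (collinear predictors)", call. = FALSE)
  }

  r2 <- vapply(fits, function(f) summary(f)$r.squared, numeric(1L))
  kf <- vapply(fits, function(f) length(stats::coef(f)) - 1L, numeric(1L))
  delta_r2 <- c(r2[1L], diff(r2))
  steps <- purrr::map_dfr(1:3, function(s) {
    if (s == 1L) {
      sm <- summary(f1)
      fstat <- sm$fstatistic
      tibble::tibble(step = 1L, r2 = r2[1L], delta_r2 = r2[1L],
                     delta_f = unname(fstat[1L]), df1 = unname(fstat[2L]),
                     df2 = unname(fstat[3L]),
                     p = stats::pf(fstat[1L], fstat[2L], fstat[3L],
                                   lower.tail = FALSE))
    } else {
      cmp <- stats::anova(fits[[s - 1L]], fits[[s]])
      tibble::tibble(step = s, r2 = r2[s], delta_r2 = delta_r2[s],
                     delta_f = cmp$F[2L], df1 = cmp$Df[2L],
                     df2 = cmp$Res.Df[2L], p = cmp$`Pr(>F)`[2L])
    }
  })

  # standardized coefficients: refit on z-scored variables
  z <- as.data.frame(scale(d[c(".y", ".age_c", ".sex", ".ab_c", ".ib_c",
                               ".abib")]))
  zf <- list(
    stats::lm(.y ~ .age_c + .sex, data = z),
    stats::lm(.y ~ .age_c + .sex + .ab_c + .ib_c, data = z),
    stats::lm(.y ~ .age_c + .sex + .ab_c + .ib_c + .abib, data = z)
  )
  label <- c(.age_c = "age", .sex = "sex", .ab_c = "ab", .ib_c = "ib",
             .abib = "ab:ib")
  coefs <- purrr::map_dfr(1:3, function(s) {
    sm <- summary(fits[[s]])$coefficients
    zb <- stats::coef(zf[[s]])
    terms <- rownames(sm)[-1L]
    tibble::tibble(
      step = s, term = unname(label[terms]),
      estimate = sm[terms, "Estimate"],
      beta = unname(zb[terms]),
      t = sm[terms, "t value"],
      p = sm[terms, "Pr(>|t|)"]
    )
  })

  out <- list(steps = steps, coefs = coefs, fits = fits, n = n,
              outcome = outcome, ab = ab, ib = ib,
              sd_ib = stats::sd(d$.ib), sd_ab = stats::sd(d$.ab))
  class(out) <- "hier_reg"
  out
}

#' @export
print.hier_reg <- function(x, ...) {
  cat(sprintf("Hierarchical regression of %s on %s, %s (n = %d)\n",
              x$outcome, x$ab, x$ib, x$n))
  print(x$steps)
  invisible(x)
}

#' Simple slopes of the attention-bias index at low and high moderator
#'
#' From the step-3 (interaction) fit on centered predictors, the slope of
#' the attention-bias index is evaluated at interpretation-bias values one
#' standard deviation below and above its mean, with standard errors from
#' the coefficient covariance matrix and t tests on the step-3 residual
#' degrees of freedom.
#'
#' @param hr A `hier_reg` object.
#' @param at Moderator offsets in SD units (default `c(-1, 1)`).
#' @return A tibble: `moderator_sd`, `slope`, `se`, `t`, `df`, `p`.
#' @examples
#' d <- tibble::tibble(y = rnorm(60), age = rnorm(60, 21, 3),
#'                     sex = rbinom(60, 1, 0.2), ab = rnorm(60),
#'                     ib = rnorm(60))
#' simple_slopes(hierarchical_regression(d, "y", "ab", "ib"))
#' @export
simple_slopes <- function(hr, at = c(-1, 1)) {
  stopifnot(inherits(hr, "hier_reg"))
  fit <- hr$fits[[3L]]
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  df <- stats::df.residual(fit)
  purrr::map_dfr(at, function(m) {
    mod <- m * hr$sd_ib
    slope <- b[".ab_c"] + b[".abib"] * mod
    se <- sqrt(V[".ab_c", ".ab_c"] + mod^2 * V[".abib", ".abib"] +
                 2 * mod * V[".ab_c", ".abib"])
    tval <- slope / se
    tibble::tibble(moderator_sd = m, slope = unname(slope), se = unname(se),
                   t = unname(tval), df = df,
                   p = 2 * stats::pt(-abs(tval), df))
  })
}
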