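#' Paired-samples t test with dz effect size
#'
#' Classical two-sided paired t test plus the within-subject effect size
#' `dz = mean(x - y) / sd(x - y)`, which satisfies `dz = t / sqrt(n)`.
#'
#' @param x,y Paired numeric vectors of equal length (n >= 2), no missing
#'   values.
#' @return An object of class `paired_t` with elements `t`, `df` (n - 1),
#'   `p`, `d_z`, `mean_diff`, `sd_diff`, `n`.
#' @examples
#' paired_t(c(9, 9.5, 8, 10), c(1, 0, 2, 0.5))
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L,
            !anyNA(x), !anyNA(y))
  d <- x - y
  if (stats::sd(d) == 0) {
    stop("zero variance of paired differences; t is degenerate",
         call. = FALSE)
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  out <- list(
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    p = ht$p.value,
    d_z = mean(d) / stats::sd(d),
    mean_diff = mean(d),
    sd_diff = stats::sd(d),
    n = length(d)
  )
  class(out) <- "paired_t"
  out
}

#' @export
print.paired_t <- function(x, ...) {
  cat(sprintf("Paired t test: t(%d) = %.2f, p = %.3g, dz = %.2f\n",
              x$df, x$t, x$p, x$d_z))
  invisible(x)
}

#' dz from a reported t statistic
#'
#' @param t Paired-samples t statistic.
#' @param n Number of pairs.
#' @return `t / sqrt(n)`.
#' @examples
#' dz_from_t(40.44, 85)
#' @export
dz_from_t <- function(t, n) t / sqrt(n)

#' Partial eta squared from an F statistic
#'
#' `F * df1 / (F * df1 + df2)`.  Invariant under Greenhouse-Geisser scaling
#' of both degrees of freedom.
#'
#' @param f F statistic.
#' @param df1,df2 Numerator and denominator degrees of freedom (raw or
#'   epsilon-scaled; the ratio is unchanged).
#' @return Partial eta squared in `[0, 1]`.
#' @examples
#' partial_eta_sq(6.52, 2, 168)
#' @export
partial_eta_sq <- function(f, df1, df2) f * df1 / (f * df1 + df2)

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fits the within-subject one-way ANOVA via [stats::aov()] with an
#' `Error(subject/condition)` stratum, estimates the Greenhouse-Geisser
#' sphericity epsilon from the sample covariance of the conditions, and
#' reports the p value from the epsilon-scaled degrees of freedom together
#' with partial eta squared.
#'
#' @param m A complete numeric matrix or data frame, one row per subject and
#'   one column per within-subject condition (k >= 2, n >= 3, no missing
#'   cells: exclude incomplete subjects listwise beforehand).
#' @return An object of class `rm_anova` with `F`, `df1`, `df2`,
#'   `gg_epsilon`, `df1_gg`, `df2_gg`, `p` (Greenhouse-Geisser corrected),
#'   `p_uncorrected`, `partial_eta2`, `n`, `k`.
#' @examples
#' m <- cbind(cs_plus = rnorm(20, 6), csa = rnorm(20, 3), cs_minus = rnorm(20, 1.5))
#' rm_anova(m)
#' @export
rm_anova <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing cells; apply listwise deletion first",
                     call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  stopifnot(n >= 3L, k >= 2L)
  df <- data.frame(
    y = as.vector(m),
    subject = factor(rep(seq_len(n), times = k)),
    condition = factor(rep(seq_len(k), each = n))
  )
  fit <- stats::aov(y ~ condition + Error(subject / condition), data = df)
  tab <- summary(fit)[["Error: subject:condition"]][[1L]]
  f <- tab["condition", "F value"]
  df1 <- tab["condition", "Df"]
  df2 <- tab["Residuals", "Df"]
  eps <- gg_epsilon(m)
  out <- list(
    F = f, df1 = df1, df2 = df2,
    gg_epsilon = eps, df1_gg = eps * df1, df2_gg = eps * df2,
    p = stats::pf(f, eps * df1, eps * df2, lower.tail = FALSE),
    p_uncorrected = stats::pf(f, df1, df2, lower.tail = FALSE),
    partial_eta2 = partial_eta_sq(f, df1, df2),
    n = n, k = k
  )
  class(out) <- "rm_anova"
  out
}

# Greenhouse-Geisser epsilon from the sample covariance of the k conditions.
gg_epsilon <- function(m) {
  S <- stats::cov(m)
  k <- ncol(S)
  sbar <- mean(S)
  dbar <- mean(diag(S))
  row_means <- rowMeans(S)
  num <- k^2 * (dbar - sbar)^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(row_means^2) + k^2 * sbar^2)
  eps <- num / den
  min(1, max(eps, 1 / (k - 1)))
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf(
    "rmANOVA (Greenhouse-Geisser): F(%.2f, %.2f) = %.2f, p = %.3g, partial eta^2 = %.3f (epsilon = %.3f)\n",
    x$df1_gg, x$df2_gg, x$F, x$p, x$partial_eta2, x$gg_epsilon))
  invisible(x)
}

#' Wilcoxon signed-rank Z
#'
#' Signed-rank test via the large-sample normal approximation, following
#' the convention used by common point-and-click statistics packages:
#' zero differences are dropped, tied absolute differences get mid-ranks,
#' the variance carries the tie correction, and no continuity correction is
#' applied.  `Z = (W - n(n+1)/4) / sigma` where `W` is the positive-rank
#' sum, so swapping `x` and `y` flips the sign of `Z`.
#'
#' @param x,y Paired numeric vectors.
#' @return A one-row tibble: `z`, `p` (two-sided), `n_nonzero`, `w_pos`.
#' @examples
#' wilcoxon_z(rnorm(20, 0.5), rnorm(20))
#' @export
wilcoxon_z <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; signed-rank test degenerate",
            call. = FALSE)
    return(tibble::tibble(z = 0, p = 1, n_nonzero = 0L, w_pos = 0))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w - mu) / sqrt(sigma2)
  tibble::tibble(z = z, p = 2 * stats::pnorm(-abs(z)), n_nonzero = n,
                 w_pos = w)
}

#' Friedman omnibus test with signed-rank follow-ups
#'
#' The nonparametric analogue of the one-way repeated-measures ANOVA for
#' metrics whose residuals are not normal (here, the gaze measures): a
#' Friedman chi-squared over the k conditions (via [stats::friedman.test()],
#' which applies the tie correction) followed by pairwise Wilcoxon
#' signed-rank Z tests on every pair of conditions.
#'
#' @inheritParams rm_anova
#' @return An object of class `friedman_battery` with `chisq`, `df`, `p`,
#'   and `pairwise` (tibble: `a`, `b`, `z`, `p`; `z` is for a - b).
#' @examples
#' m <- cbind(a = rnorm(15, 1), b = rnorm(15), c = rnorm(15))
#' friedman_wilcoxon(m)
#' @export
friedman_wilcoxon <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing cells; apply listwise deletion first",
                     call. = FALSE)
  k <- ncol(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(k))
  ft <- stats::friedman.test(m)
  pairs <- utils::combn(colnames(m), 2L)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    dplyr::mutate(wilcoxon_z(m[, a], m[, b]), a = a, b = b, .before = 1L)
  })
  out <- list(chisq = unname(ft$statistic), df = unname(ft$parameter),
              p = ft$p.value, pairwise = pairwise)
  class(out) <- "friedman_battery"
  out
}

#' @export
print.friedman_battery <- function(x, ...) {
  cat(sprintf("Friedman: chi^2(%d) = %.2f, p = %.3g\n", x$df, x$chisq, x$p))
  print(x$pairwise)
  invisible(x)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Two-sided test of zero correlation with the 95% (by default) confidence
#' interval from the Fisher z transform with standard error
#' `1 / sqrt(n - 3)`.
#'
#' @param x,y Numeric vectors (n >= 4), no missing values.
#' @param conf_level Confidence level for the interval.
#' @return A one-row tibble: `r`, `t`, `df`, `p`, `ci_low`, `ci_high`, `n`.
#' @examples
#' pearson_ci(rnorm(50), rnorm(50))
#' @export
pearson_ci <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 4L, !anyNA(x), !anyNA(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance; correlation undefined", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, conf.level = conf_level)
  tibble::tibble(
    r = unname(ht$estimate),
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    p = ht$p.value,
    ci_low = ht$conf.int[1L],
    ci_high = ht$conf.int[2L],
    n = length(x)
  )
}
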