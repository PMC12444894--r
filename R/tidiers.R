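#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy methods for painbias result objects
#'
#' Broom-style one-row-per-term summaries of the package's fitted objects.
#'
#' @param x A `paired_t`, `rm_anova`, `friedman_battery`, `hier_reg` or
#'   `cohort_analysis` object.
#' @param ... Unused.
#' @return A tibble.
#' @name painbias-tidiers
NULL

#' @rdname painbias-tidiers
#' @export
tidy.paired_t <- function(x, ...) {
  tibble::tibble(t = x$t, df = x$df, p.value = x$p, d_z = x$d_z,
                 mean_diff = x$mean_diff, n = x$n)
}

#' @rdname painbias-tidiers
#' @export
tidy.rm_anova <- function(x, ...) {
  tibble::tibble(F = x$F, df1 = x$df1_gg, df2 = x$df2_gg,
                 p.value = x$p, partial_eta2 = x$partial_eta2,
                 gg_epsilon = x$gg_epsilon)
}

#' @rdname painbias-tidiers
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(n = x$n, k = x$k, gg_epsilon = x$gg_epsilon,
                 p.value = x$p, p.uncorrected = x$p_uncorrected)
}

#' @rdname painbias-tidiers
#' @export
tidy.friedman_battery <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(test = "friedman", a = NA_character_, b = NA_character_,
                   statistic = x$chisq, p.value = x$p),
    dplyr::transmute(x$pairwise, test = "wilcoxon", a = .data$a, b = .data$b,
                     statistic = .data$z, p.value = .data$p)
  )
}

#' @rdname painbias-tidiers
#' @export
tidy.hier_reg <- function(x, ...) {
  dplyr::rename(x$coefs, p.value = "p", statistic = "t")
}

#' @rdname painbias-tidiers
#' @export
glance.hier_reg <- function(x, ...) {
  dplyr::rename(x$steps, p.value = "p")
}

#' @rdname painbias-tidiers
#' @export
tidy.cohort_analysis <- function(x, ...) {
  idx <- index_names()
  tibble::tibble(
    index = idx,
    mean = colMeans(x$data[idx]),
    sd = vapply(x$data[idx], stats::sd, numeric(1L)),
    n = nrow(x$data)
  )
}

#' @rdname painbias-tidiers
#' @export
glance.cohort_analysis <- function(x, ...) x$exclusions
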