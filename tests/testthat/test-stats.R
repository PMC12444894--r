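test_that("paired t equals a one-sample t on differences and dz = t/sqrt(n)", {
  withr::with_seed(71, {
    for (i in 1:10) {
      n <- sample(10:60, 1L)
      x <- rnorm(n); y <- rnorm(n, 0.3)
      got <- paired_t(x, y)
      ref <- t.test(x - y)
      expect_equal(got$t, unname(ref$statistic))
      expect_equal(got$p, ref$p.value)
      expect_equal(got$d_z, got$t / sqrt(n), tolerance = 1e-9)
    }
  })
  expect_error(paired_t(1:5, 1:5 + 2), "zero variance")
  expect_equal(round(dz_from_t(40.44, 85), 2), 4.39)
})

test_that("rmANOVA matches the multivariate-model reference including GG correction", {
  skip_if_not_installed("car")
  withr::with_seed(72, {
    for (i in 1:5) {
      n <- sample(12:40, 1L)
      m <- matrix(rnorm(n * 3), n, 3) %*% chol(matrix(c(1, .5, .2,
                                                        .5, 1.3, .4,
                                                        .2, .4, .9), 3)) +
        rep(c(0, 0.3, 0.5), each = n)
      got <- rm_anova(m)
      fit <- stats::lm(m ~ 1)
      av <- suppressWarnings(
        summary(car::Anova(fit, idata = data.frame(cond = factor(1:3)),
                           idesign = ~cond), multivariate = FALSE))
      adj <- av$pval.adjustments
      expect_equal(got$gg_epsilon, unname(adj[1, "GG eps"]), tolerance = 1e-10)
      expect_equal(got$p, unname(adj[1, "Pr(>F[GG])"]), tolerance = 1e-10)
      un <- av$univariate.tests
      fcol <- grep("^F", colnames(un), value = TRUE)[1]
      expect_equal(got$F, unname(un["cond", fcol]), tolerance = 1e-10)
    }
  })
})

test_that("partial eta squared reproduces reported effect sizes and is GG-invariant", {
  expect_equal(round(partial_eta_sq(6.52, 2, 168), 2), 0.07)
  expect_equal(round(partial_eta_sq(268.42, 1.43, 120.31), 2), 0.76)
  eps <- 0.77
  expect_equal(partial_eta_sq(5, 2, 80), partial_eta_sq(5, 2 * eps, 80 * eps))
})

test_that("epsilon approaches 1 under compound symmetry and respects its bounds", {
  withr::with_seed(73, {
    eps <- replicate(40, {
      subj <- rnorm(60, sd = 1.5)
      m <- matrix(rnorm(180, sd = 0.8), 60, 3) + subj
      rm_anova(m)$gg_epsilon
    })
    expect_gt(mean(eps), 0.9)
    expect_true(all(eps >= 0.5 & eps <= 1))
  })
})

test_that("Friedman reaches its enumerable maximum on rank-identical data", {
  withr::with_seed(74, {
    m <- cbind(a = rnorm(10, 10), b = rnorm(10), c = rnorm(10, -10))
    fr <- friedman_wilcoxon(m)
    # closed form 12 n (k - 1) / (k (k + 1)) for consistent orderings
    expect_equal(fr$chisq, 12 * 10 * 2 / (3 * 4))
    expect_equal(fr$df, 2L)
    expect_equal(nrow(fr$pairwise), 3L)
  })
})

test_that("signed-rank Z matches the exhaustive-enumeration oracle", {
  withr::with_seed(75, {
    for (i in 1:25) {
      n <- sample(5:11, 1L)
      x <- sample(0:8, n, replace = TRUE)
      y <- sample(0:8, n, replace = TRUE)
      if (all(x == y)) x[1] <- x[1] + 1L
      got <- wilcoxon_z(x, y)
      expect_equal(got$z, slow_signed_rank_z(x, y), tolerance = 1e-12)
      # antisymmetry under swapping the members of each pair
      expect_equal(wilcoxon_z(y, x)$z, -got$z, tolerance = 1e-12)
    }
  })
  expect_warning(out <- wilcoxon_z(1:5, 1:5), "degenerate")
  expect_equal(out$z, 0)
})

test_that("signed-rank p agrees with the classical normal approximation", {
  withr::with_seed(76, {
    x <- rnorm(40); y <- rnorm(40, 0.4)
    got <- wilcoxon_z(x, y)
    ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = FALSE)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  })
})

test_that("Pearson CI follows the Fisher-z construction", {
  withr::with_seed(77, {
    x <- rnorm(50); y <- 0.4 * x + rnorm(50)
    got <- pearson_ci(x, y)
    r <- cor(x, y)
    z <- atanh(r) + c(-1, 1) * qnorm(0.975) / sqrt(50 - 3)
    expect_equal(got$r, r)
    expect_equal(c(got$ci_low, got$ci_high), tanh(z), tolerance = 1e-10)
    expect_true(got$ci_low <= got$r && got$r <= got$ci_high)
  })
  # the reported-style interval: r = 0.22 with n = 85 rounds to [0.01, 0.41]
  ci <- tanh(atanh(0.22) + c(-1, 1) * qnorm(0.975) / sqrt(82))
  expect_equal(round(ci, 2), c(0.01, 0.41))
  expect_error(pearson_ci(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("CI coverage is close to nominal under bivariate normal sampling", {
  withr::with_seed(78, {
    rho <- 0.3; n <- 85; reps <- 600
    covered <- replicate(reps, {
      x <- rnorm(n)
      y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
      ci <- pearson_ci(x, y)
      ci$ci_low <= rho && rho <= ci$ci_high
    })
    expect_gt(mean(covered), 0.91)
    expect_lt(mean(covered), 0.99)
  })
})

test_that("hierarchical regression builds nested models with correct increments", {
  withr::with_seed(79, {
    n <- 85
    d <- tibble::tibble(
      age = rnorm(n, 21, 5), sex = rbinom(n, 1, 0.15),
      ab = rnorm(n), ib = rnorm(n))
    d$y <- d$ab  # outcome identical to the attention-bias index
    hr <- suppressWarnings(hierarchical_regression(d, "y", "ab", "ib"))
    expect_equal(hr$steps$r2[2], 1)
    expect_equal(hr$steps$delta_r2[2], 1 - hr$steps$r2[1], tolerance = 1e-9)
    expect_equal(abs(hr$coefs$beta[hr$coefs$step == 2 &
                                     hr$coefs$term == "ab"]), 1,
                 tolerance = 1e-6)
    # R^2 never decreases across steps
    expect_true(all(diff(hr$steps$r2) >= -1e-12))
    # the step increments agree with stats::anova on the stored fits
    cmp <- anova(hr$fits[[2]], hr$fits[[3]])
    expect_equal(hr$steps$delta_f[3], cmp$F[2])
    # rank deficiency is reported
    d2 <- d; d2$ib <- d2$ab
    expect_error(hierarchical_regression(d2, "y", "ab", "ib"),
                 "rank-deficient")
  })
})

test_that("step increments have uniform p-values under the null", {
  withr::with_seed(80, {
    ps <- replicate(1000, {
      n <- 30
      d <- tibble::tibble(y = rnorm(n), age = rnorm(n, 21, 4),
                          sex = rbinom(n, 1, 0.5), ab = rnorm(n),
                          ib = rnorm(n))
      hierarchical_regression(d, "y", "ab", "ib")$steps$p[2]
    })
    expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  })
})

test_that("a real interaction is detected and read out by simple slopes", {
  withr::with_seed(81, {
    hits <- replicate(60, {
      n <- 85
      d <- tibble::tibble(age = rnorm(n, 21, 4), sex = rbinom(n, 1, 0.2),
                          ab = rnorm(n), ib = rnorm(n))
      d$y <- as.numeric(0.3 * scale(d$ab, scale = FALSE) *
                          scale(d$ib, scale = FALSE)) + rnorm(n, sd = 0.5)
      hierarchical_regression(d, "y", "ab", "ib")$steps$p[3] < 0.05
    })
    expect_gt(mean(hits), 0.8)
    # crossover interaction: slopes of opposite sign at -1/+1 SD
    n <- 400
    d <- tibble::tibble(age = rnorm(n, 21, 4), sex = rbinom(n, 1, 0.2),
                        ab = rnorm(n), ib = rnorm(n))
    d$y <- as.numeric(0.8 * scale(d$ab, scale = FALSE) *
                        scale(d$ib, scale = FALSE)) + rnorm(n, sd = 0.3)
    hr <- hierarchical_regression(d, "y", "ab", "ib")
    sl <- simple_slopes(hr)
    expect_lt(sl$slope[sl$moderator_sd == -1], 0)
    expect_gt(sl$slope[sl$moderator_sd == 1], 0)
  })
})

test_that("simple slopes reproduce the arithmetic of the interaction fit", {
  withr::with_seed(82, {
    n <- 200
    d <- tibble::tibble(age = rnorm(n, 21, 4), sex = rbinom(n, 1, 0.2),
                        ab = rnorm(n), ib = rnorm(n))
    ab_c <- d$ab - mean(d$ab); ib_c <- d$ib - mean(d$ib)
    d$y <- 1 * ab_c + 0.5 * ab_c * ib_c  # exact, noiseless coefficients
    hr <- suppressWarnings(hierarchical_regression(d, "y", "ab", "ib"))
    sl <- suppressWarnings(simple_slopes(hr))
    sd_ib <- sd(d$ib)
    expect_equal(sl$slope, 1 + 0.5 * c(-1, 1) * sd_ib, tolerance = 1e-8)
    # zero interaction: both slopes equal the main effect
    d$y <- 2 * ab_c + rnorm(n, sd = 1e-8)
    sl0 <- simple_slopes(
      suppressWarnings(hierarchical_regression(d, "y", "ab", "ib")))
    expect_equal(sl0$slope, c(2, 2), tolerance = 1e-4)
  })
})

test_that("tidy and glance methods return the documented shapes", {
  withr::with_seed(83, {
    x <- rnorm(20); y <- rnorm(20, 0.5)
    expect_named(tidy(paired_t(x, y)),
                 c("t", "df", "p.value", "d_z", "mean_diff", "n"))
    m <- matrix(rnorm(45), 15, 3)
    expect_true(all(c("F", "partial_eta2") %in% names(tidy(rm_anova(m)))))
    td <- tidy(friedman_wilcoxon(m))
    expect_equal(td$test, c("friedman", rep("wilcoxon", 3)))
  })
})
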