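# balanced nested ANOVA estimator, within-day ACF, block-variance deflation

test_that("the hand-worked 2x2x2 example is reproduced to machine precision", {
  # subject A: days (1,3), (5,7); subject B: days (9,11), (13,15)
  y <- array(c(1, 3, 5, 7, 9, 11, 13, 15), c(2, 2, 2))
  fit <- estimate_varcomp(y)
  expect_identical(fit$mu, 8)
  expect_identical(unname(fit$ms), c(128, 16, 2))
  expect_identical(unname(fit$components), c(28, 7, 2))
  expect_identical(fit$raw, fit$components)
  expect_identical(unname(fit$df), c(1L, 2L, 4L))
  expect_equal(coef(fit), c(mu = 8, var_bs = 28, var_bd = 7, var_wd = 2))
})

test_that("a constant data set has zero components and mu equal to the constant", {
  y <- array(5.5, c(3, 2, 2))
  fit <- estimate_varcomp(y)
  expect_equal(fit$mu, 5.5)
  expect_equal(unname(fit$components), c(0, 0, 0))
})

test_that("mean squares reconstruct the strata sums of squares on random input", {
  set.seed(21)
  for (r in 1:5) {
    dims <- c(sample(2:6, 1), sample(2:5, 1), sample(2:7, 1)) # n, d, a
    y <- array(rnorm(prod(dims), sd = 3), dims)
    fit <- estimate_varcomp(y)
    o <- anova_oracle(y)
    expect_equal(unname(fit$ms), c(o$MS_S, o$MS_D, o$MS_E), tolerance = 1e-12)
    # partition identity: strata SS add up to the total SS about the grand mean
    n <- dims[1]; d <- dims[2]; a <- dims[3]
    ss <- (a - 1) * fit$ms[["MS_S"]] + a * (d - 1) * fit$ms[["MS_D"]] +
      a * d * (n - 1) * fit$ms[["MS_E"]]
    expect_equal(ss, sum((y - mean(y))^2), tolerance = 1e-10)
  }
})

test_that("clipped estimates agree with REML (lme4) on balanced data with interior optimum", {
  skip_if_not_installed("lme4")
  set.seed(31)
  prof <- iid_profile(mu = 10, var_bs = 25, var_bd = 9, var_wd = 4)
  pd <- generate_parent(prof, n_subjects = 8, n_days = 3, day_length = 12, seed = 31)
  fit <- estimate_varcomp(pd)
  df <- as.data.frame(pd)
  ctl <- lme4::lmerControl(optimizer = "bobyqa")
  m <- lme4::lmer(value ~ 1 + (1 | subject) + (1 | subject:day), data = df,
                  REML = TRUE, control = ctl)
  vc <- as.data.frame(lme4::VarCorr(m))
  reml <- c(var_bs = vc$vcov[vc$grp == "subject"],
            var_bd = vc$vcov[vc$grp == "subject:day"],
            var_wd = vc$vcov[vc$grp == "Residual"])
  skip_if(any(reml < 1e-8), "REML solution on the boundary")
  expect_equal(fit$components[names(reml)], reml, tolerance = 1e-6)
  expect_equal(fit$mu, unname(lme4::fixef(m)[1]), tolerance = 1e-8)
})

test_that("unbalanced or degenerate inputs are rejected", {
  expect_error(estimate_varcomp(array(1, c(1, 2, 2))), "at least 2")
  expect_error(estimate_varcomp(array(1, c(2, 1, 2))), "at least 2")
  df <- toy_long(2, 2, 4)
  expect_error(estimate_varcomp(df[-1, ]), "balanced")
})

test_that("raw ANOVA estimators are unbiased under independent errors", {
  set.seed(41)
  truth <- c(var_bs = 3, var_bd = 4, var_wd = 16)
  reps <- 4000
  est <- matrix(0, reps, 3)
  a <- 6L; d <- 3L; n <- 12L
  for (r in seq_len(reps)) {
    y <- array(rnorm(n * d * a, sd = sqrt(truth["var_wd"])), c(n, d, a)) +
      rep(rnorm(a, sd = sqrt(truth["var_bs"])), each = n * d) +
      rep(rnorm(a * d, sd = sqrt(truth["var_bd"])), each = n)
    est[r, ] <- estimate_varcomp(y)$raw
  }
  se <- apply(est, 2, sd) / sqrt(reps)
  dev <- abs(colMeans(est) - truth)
  expect_true(all(dev < 3 * se),
              info = paste("deviations", paste(round(dev, 3), collapse = " "),
                           "vs 3se", paste(round(3 * se, 3), collapse = " ")))
})

test_that("within-day ACF: white noise, exact alternation, and AR(1) recovery", {
  set.seed(51)
  # iid noise: every lag near zero
  y <- array(rnorm(200 * 4 * 6), c(200, 4, 6))
  a0 <- within_day_acf(y, lags = c(1, 5, 10))
  expect_true(all(abs(a0$acf) < 0.05))
  expect_equal(a0$n_series, 24)

  # exact alternation of even length n has sample ACF(1) = -(n-1)/n... scaled
  n <- 100
  alt <- rep(c(1, -1), n / 2)
  y1 <- array(rep(alt, 4), c(n, 2, 2))
  a1 <- within_day_acf(y1, lags = 1)
  expect_equal(unname(a1$acf), -(n - 1) / n, tolerance = 1e-12)

  # AR(1) phi = 0.5 over many 480-minute days: mean sample ACF(1) near 0.5
  phi <- 0.5
  days <- 60
  e <- matrix(0, 480, days)
  for (j in seq_len(days))
    e[, j] <- stats::filter(rnorm(480, sd = sqrt(1 - phi^2)), phi, "recursive",
                            init = rnorm(1))
  a2 <- within_day_acf(array(e, c(480, days, 1)), lags = 1)
  expect_lt(abs(a2$acf[["1"]] - phi), 0.02)

  # zero-variance days are skipped with a warning
  yz <- array(rnorm(50 * 2 * 2), c(50, 2, 2))
  yz[, 1, 1] <- 7
  expect_warning(az <- within_day_acf(yz, lags = 1), "zero-variance")
  expect_equal(az$n_series, 3)
})

test_that("block variance deflation factor: closed-form cases and Monte-Carlo oracle", {
  expect_identical(expected_block_variance_factor(10, rep(0, 9)), 1)
  expect_identical(expected_block_variance_factor(2, 0.5), 0.5)
  expect_error(expected_block_variance_factor(1, 0.5), "at least 2")

  prof <- gt90_profile()
  n <- 60
  f <- expected_block_variance_factor(n, prof)
  expect_lt(f, 1)
  expect_gt(f, 0)
  # Monte-Carlo oracle: mean sample variance of single contiguous blocks
  set.seed(61)
  v_wd <- prof$latent[["var_wd"]]
  reps <- 4000
  s2 <- numeric(reps)
  for (r in seq_len(reps))
    s2[r] <- stats::var(postvar:::generate_error_stream(prof$mixture, v_wd, n,
                                                        seed = sample.int(2^30, 1)))
  se <- sd(s2) / sqrt(reps)
  expect_lt(abs(mean(s2) - v_wd * f), 3 * se)
})
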