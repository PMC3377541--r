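# three-level bootstrap engine

make_parent <- function(seed = 1, a = 6, d = 4, n = 480,
                        profile = gt90_profile()) {
  generate_parent(profile, n_subjects = a, n_days = d, day_length = n, seed = seed)
}

test_that("bootstrap samples have the prescribed shape and verbatim parent values", {
  parent <- make_parent(seed = 2, a = 5, d = 4, n = 480)
  st <- sampling_strategy(10, 120, 2, 15, "random")
  set.seed(101)
  bs <- draw_bootstrap_sample(parent, st)
  expect_s3_class(bs, "parent_data")
  expect_equal(dim(bs), c(60, 2, 10))
  expect_true(all(as.numeric(bs) %in% as.numeric(parent)))

  # exhausting the parent's days: every drawn subject contributes each parent
  # day exactly once, as verbatim full-day columns
  st_all <- sampling_strategy(4, 1920, 4, 480, "random", day_length = 480)
  bs2 <- draw_bootstrap_sample(parent, st_all)
  parent_cols <- apply(unclass(parent), c(2, 3), paste, collapse = ",")
  for (i in 1:4) {
    cols <- apply(unclass(bs2)[, , i], 2, paste, collapse = ",")
    expect_true(all(cols %in% parent_cols))
    expect_equal(anyDuplicated(cols), 0)
  }
  expect_error(draw_bootstrap_sample(parent, sampling_strategy(2, 60, 6, 1, "random")),
               "more days")
})

test_that("per-day minutes come as non-overlapping time-ordered blocks", {
  parent <- parent_data(array(seq_len(480 * 2 * 2), c(480, 2, 2)), "idx")
  st <- sampling_strategy(3, 120, 2, 15, "fixed")
  set.seed(7)
  bs <- draw_bootstrap_sample(parent, st)
  # values encode the parent minute index, so positions are recoverable
  for (i in 1:3) for (j in 1:2) {
    mins <- (unclass(bs)[, j, i] - 1) %% 480
    expect_true(all(diff(mins) >= 1))              # strictly increasing
    starts <- mins[seq(1, 60, by = 15)]
    expect_true(all(diff(starts) == 120))          # fixed-interval comb
  }
})

test_that("bias and prediction intervals follow their definitions", {
  expect_equal(bias(c(1, 2, 3), 1), 1)
  expect_equal(bias(rep(5, 10), 5), 0)
  expect_error(bias(numeric(0), 1), "no estimates")

  expect_equal(prediction_interval(rep(2, 50), truth = 2), c(low = 0, high = 0))
  expect_error(prediction_interval(1:10, 0), "at least 20")

  # uniform draws: 5th/95th percentiles near 0.05 and 0.95 (3 SE of the
  # order statistic, f = 1 for the uniform density)
  set.seed(111)
  u <- runif(5000)
  pi_u <- prediction_interval(u, truth = 0)
  se <- sqrt(0.05 * 0.95 / 5000)
  expect_lt(abs(pi_u[["low"]] - 0.05), 3 * se)
  expect_lt(abs(pi_u[["high"]] - 0.95), 3 * se)

  # boundary mass: >= 5% of clipped estimates at zero pins the lower bound at -truth
  est <- c(rep(0, 400), runif(4600, 1, 9))
  expect_identical(prediction_interval(est, truth = 3)[["low"]], -3)
})

test_that("strategy runs are reproducible and expose the parent truth", {
  parent <- make_parent(seed = 3, a = 5, d = 4, n = 240)
  st <- sampling_strategy(8, 60, 2, 15, "random")
  r1 <- run_strategy(parent, st, n_reps = 60, seed = 5)
  r2 <- run_strategy(parent, st, n_reps = 60, seed = 5)
  expect_identical(r1$table, r2$table)
  expect_equal(unname(r1$truth), unname(coef(estimate_varcomp(parent))))
  expect_identical(dim(r1$percentiles), c(99L, 3L))
  # prediction intervals are ordered and respect the clipping floor
  with(r1$table, {
    expect_true(all(pi_low <= pi_high))
    expect_true(all(pi_low >= -truth - 1e-12))
  })
})

test_that("a grid run crosses variables and strategies deterministically", {
  p1 <- make_parent(seed = 4, a = 4, d = 4, n = 120)
  p2 <- make_parent(seed = 5, a = 4, d = 4, n = 120,
                    profile = iid_profile(mu = 1, name = "iid_var"))
  strategies <- enumerate_strategies(n_s = 5, t_tot = c(60, 120), n_d = 2,
                                     t_b = c(15, 30), day_length = 120)
  rep1 <- run_grid(list(p1, p2), strategies, n_reps = 40, seed = 6)
  rep2 <- run_grid(list(p1, p2), strategies, n_reps = 40, seed = 6)
  expect_identical(rep1$table, rep2$table)
  expect_equal(nrow(rep1$table), nrow(strategies) * 2 * 3)
  expect_setequal(unique(rep1$table$variable), c("pct_above_90", "iid_var"))
  expect_true(all(c("variable", "n_s", "t_tot", "n_d", "t_b", "dispersion",
                    "component", "bias", "pi_low", "pi_high", "mean_estimate",
                    "truth", "n_reps") %in% names(rep1$table)))
  tmp <- tempfile(fileext = ".csv")
  write_report_csv(rep1, tmp)
  back <- read.csv(tmp)
  expect_equal(nrow(back), nrow(rep1$table))
  expect_warning(empty <- run_grid(p1, strategies[0, ]), "empty")
  expect_equal(nrow(empty$table), 0)
})

test_that("nested prediction-interval coverage is close to nominal", {
  parent <- make_parent(seed = 8, a = 8, d = 4, n = 240)
  st <- sampling_strategy(6, 60, 2, 15, "random")
  ref <- run_strategy(parent, st, n_reps = 1000, seed = 9, keep_estimates = TRUE)
  fresh <- run_strategy(parent, st, n_reps = 500, seed = 10, keep_estimates = TRUE)
  for (cc in c("var_bs", "var_bd", "var_wd")) {
    row <- ref$table[ref$table$component == sub("var_", "", cc), ]
    inside <- mean(fresh$estimates[, cc] >= row$truth + row$pi_low &
                     fresh$estimates[, cc] <= row$truth + row$pi_high)
    # binomial SE at n = 500 plus quantile-estimation noise in the interval
    expect_lt(abs(inside - 0.9), 0.05)
  }
})
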