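# Shared fixtures, all generated in code.

# study ACF targets for percentage time above 90 degrees
acf_targets_gt90 <- c(`1` = 0.52, `2` = 0.34, `3` = 0.26,
                      `4` = 0.22, `5` = 0.17, `10` = 0.08)

# profile with independent within-day errors (no calibration involved)
iid_profile <- function(mu = 0, var_bs = 3, var_bd = 4, var_wd = 164.7,
                        name = "iid") {
  posture_profile(name, mu = mu, var_bs = var_bs, var_bd = var_bd,
                  var_wd = var_wd, acf_targets = NULL)
}

# the calibrated percentage-time-above-90 study profile (cached by the package)
gt90_profile <- function() default_profile("car_mechanics_pct_gt90")

# small deterministic balanced long table: value = coded by (subject, day, minute)
toy_long <- function(n_sub = 2, n_day = 2, n_min = 4) {
  g <- expand.grid(minute = seq_len(n_min) - 1L, day = seq_len(n_day),
                   subject = paste0("S", seq_len(n_sub)))
  data.frame(subject = g$subject, day = g$day, minute = g$minute,
             value = as.numeric(100 * match(g$subject, unique(g$subject)) +
                                  10 * g$day + g$minute))
}

# mean-squares by the textbook sums (independent slow oracle for the fitter)
anova_oracle <- function(y) {
  n <- dim(y)[1]; d <- dim(y)[2]; a <- dim(y)[3]
  grand <- mean(y)
  ss_s <- 0; ss_d <- 0; ss_e <- 0
  for (i in seq_len(a)) {
    mi <- mean(y[, , i])
    ss_s <- ss_s + d * n * (mi - grand)^2
    for (j in seq_len(d)) {
      mij <- mean(y[, j, i])
      ss_d <- ss_d + n * (mij - mi)^2
      ss_e <- ss_e + sum((y[, j, i] - mij)^2)
    }
  }
  list(MS_S = ss_s / (a - 1), MS_D = ss_d / (a * (d - 1)),
       MS_E = ss_e / (a * d * (n - 1)), mu = grand)
}
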