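#' Generate a synthetic balanced parent data set
#'
#' Realizes the hierarchical random-effects model
#' `y_ijk = mu + a_i + b_ij + e_ijk` with Gaussian subject effects
#' `a_i ~ N(0, var_bs)`, day-within-subject effects `b_ij ~ N(0, var_bd)` and
#' a stationary, serially correlated within-day error process `e_ij.` with
#' marginal variance `var_wd` and autocorrelation
#' `w * phi1^k + (1 - w) * phi2^k` — the sum of two independent AR(1)
#' streams carrying variances `w * var_wd` and `(1 - w) * var_wd`, each
#' started from its stationary distribution. Days are independent given the
#' day effect, and the latent variances/mixture come from the profile's
#' calibration (see [posture_profile()]), so that full-data estimates of the
#' components and the day-averaged sample ACF recover the profile's stated
#' values in expectation.
#'
#' Reproducibility: one master seed; per-day error streams use child seeds
#' drawn up-front from the master stream, indexed by (subject, day), so any
#' single day can be regenerated in isolation.
#'
#' @param profile a [posture_profile()].
#' @param n_subjects,n_days,day_length dimensions of the generated data set;
#'   defaults match a 23-subject, 4-day, 480-minute parent.
#' @param seed integer master seed.
#' @return a [parent_data()].
#' @examples
#' prof <- posture_profile("toy", mu = 0, var_bs = 1, var_bd = 1, var_wd = 4,
#'                         acf_targets = NULL)
#' generate_parent(prof, n_subjects = 3, n_days = 2, day_length = 60, seed = 1)
#' @export
generate_parent <- function(profile, n_subjects = 23L, n_days = 4L,
                            day_length = 480L, seed = 1L) {
  stopifnot(inherits(profile, "posture_profile"))
  if (n_subjects < 1 || n_days < 1 || day_length < 1)
    stop("n_subjects, n_days and day_length must be positive", call. = FALSE)
  set.seed(seed)
  a <- n_subjects; d <- n_days; n <- day_length
  lat <- profile$latent
  ai <- stats::rnorm(a, sd = sqrt(lat["var_bs"]))
  bij <- matrix(stats::rnorm(a * d, sd = sqrt(lat["var_bd"])), d, a)
  child_seeds <- matrix(sample.int(.Machine$integer.max, a * d), d, a)
  y <- array(0, c(n, d, a))
  for (i in seq_len(a)) for (j in seq_len(d)) {
    e <- generate_error_stream(profile$mixture, lat["var_wd"], n, child_seeds[j, i])
    y[, j, i] <- profile$mu + ai[i] + bij[j, i] + e
  }
  if (!is.null(profile$clip_bounds))
    y[] <- pmin(pmax(y, profile$clip_bounds[1]), profile$clip_bounds[2])
  parent_data(y, variable_name = profile$variable_name)
}

# one stationary day of the two-AR(1) error mixture, marginal variance var_wd
generate_error_stream <- function(mixture, var_wd, n, seed) {
  set.seed(seed)
  s1 <- sqrt(mixture$w * var_wd)
  s2 <- sqrt((1 - mixture$w) * var_wd)
  e <- ar1_stream(n, mixture$phi1, s1) + ar1_stream(n, mixture$phi2, s2)
  as.numeric(e)
}

ar1_stream <- function(n, phi, sd_marginal) {
  if (sd_marginal == 0) return(numeric(n))
  if (phi == 0) return(stats::rnorm(n, sd = sd_marginal))
  init <- stats::rnorm(1, sd = sd_marginal)
  innov <- stats::rnorm(n, sd = sd_marginal * sqrt(1 - phi^2))
  stats::filter(innov, phi, method = "recursive", init = init)
}

#' Simulate one day of 1-Hz inclinometer interval codes
#'
#' Produces a synthetic stream of arm-elevation interval codes as recorded by
#' a 1-Hz inclinometer that bins the elevation angle into six 15-degree
#' intervals from 0 to 90 degrees plus a seventh interval for angles above
#' 90 degrees. A latent non-negative angle trace is simulated as a
#' mean-reverting AR(1) (reflected at 0) and binned at thresholds
#' 15, 30, ..., 90. Optional missing-data gaps (coded `NA`) can be inserted
#' at random positions to exercise gap repair.
#'
#' @param duration_s stream length in seconds.
#' @param mean_angle latent mean elevation (degrees).
#' @param sd_angle latent marginal standard deviation (degrees); `0` gives a
#'   constant trace.
#' @param phi 1-Hz AR(1) coefficient of the latent trace.
#' @param n_gaps,gap_length_s number and length of missing segments.
#' @param seed integer seed.
#' @return integer vector of codes in `1..7`, with `NA` for missing seconds.
#' @examples
#' table(generate_abduflex_day(600, mean_angle = 50, sd_angle = 0, seed = 1))
#' @export
generate_abduflex_day <- function(duration_s, mean_angle = 30, sd_angle = 20,
                                  phi = 0.995, n_gaps = 0L, gap_length_s = 60L,
                                  seed = 1L) {
  if (duration_s < 1) stop("duration_s must be positive", call. = FALSE)
  stopifnot(mean_angle >= 0, sd_angle >= 0, abs(phi) < 1)
  set.seed(seed)
  angle <- abs(mean_angle + as.numeric(ar1_stream(duration_s, phi, sd_angle)))
  codes <- findInterval(angle, c(15, 30, 45, 60, 75, 90)) + 1L
  if (n_gaps > 0) {
    for (g in seq_len(n_gaps)) {
      start <- sample.int(max(1L, duration_s - gap_length_s + 1L), 1L)
      codes[start:min(duration_s, start + gap_length_s - 1L)] <- NA_integer_
    }
  }
  codes
}
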