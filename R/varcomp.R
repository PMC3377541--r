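#' Estimate variance components of a balanced three-level data set
#'
#' Fits the hierarchical random-effects model
#' `y_ijk = mu + a_i + b_ij + e_ijk` (subjects / days within subjects /
#' minutes within days) to a fully balanced data set by the expected
#' mean-squares (ANOVA) method, which coincides with REML on balanced data
#' whenever the REML solution is interior. With `a` subjects, `d` days and
#' `n` minutes per day:
#' \deqn{MS_S = dn \sum_i (\bar y_{i..} - \bar y_{...})^2 / (a - 1)}
#' \deqn{MS_D = n \sum_{ij} (\bar y_{ij.} - \bar y_{i..})^2 / (a(d - 1))}
#' \deqn{MS_E = \sum_{ijk} (y_{ijk} - \bar y_{ij.})^2 / (ad(n - 1))}
#' and the raw moment estimators are `sigma2_WD = MS_E`,
#' `sigma2_BD = (MS_D - MS_E)/n`, `sigma2_BS = (MS_S - MS_D)/(dn)`. Negative
#' raw values are clipped at zero in the reported components (mimicking the
#' boundary behavior of an REML fitter); raw values are retained for
#' diagnostics.
#'
#' @param x a [parent_data()], a 3-d numeric array `(minute, day, subject)`,
#'   or a long data.frame with columns `subject`, `day`, `minute`, `value`
#'   describing a balanced design.
#' @param ... unused.
#' @return object of class `varcomp` with elements `mu`, `components`
#'   (clipped, named `var_bs`, `var_bd`, `var_wd`), `raw`, `ms` (the three
#'   mean squares), `df` (degrees of freedom per stratum), `dims`
#'   (`a`, `d`, `n`) and `variable_name`. Methods: `print`, `summary`,
#'   `coef`, `simulate`.
#' @examples
#' y <- array(c(1, 3, 5, 7, 9, 11, 13, 15), c(2, 2, 2))
#' coef(estimate_varcomp(y)) # mu 8, var_bs 28, var_bd 7, var_wd 2
#' @export
estimate_varcomp <- function(x, ...) UseMethod("estimate_varcomp")

#' @export
estimate_varcomp.parent_data <- function(x, ...) {
  out <- varcomp_from_array(unclass(x))
  out$variable_name <- attr(x, "variable_name")
  out
}

#' @export
estimate_varcomp.array <- function(x, ...) varcomp_from_array(x)

#' @export
estimate_varcomp.data.frame <- function(x, ...) {
  pd <- long_to_parent(x)
  estimate_varcomp(pd)
}

varcomp_from_array <- function(y) {
  dm <- dim(y)
  if (length(dm) != 3L) stop("expected a 3-d array (minute, day, subject)", call. = FALSE)
  n <- dm[1]; d <- dm[2]; a <- dm[3]
  if (a < 2 || d < 2 || n < 2)
    stop("need at least 2 subjects, 2 days and 2 minutes per day", call. = FALSE)
  ms <- varcomp_ms(y)
  raw <- c(var_bs = (ms[["MS_S"]] - ms[["MS_D"]]) / (d * n),
           var_bd = (ms[["MS_D"]] - ms[["MS_E"]]) / n,
           var_wd = ms[["MS_E"]])
  structure(list(mu = ms[["mu"]],
                 components = pmax(raw, 0),
                 raw = raw,
                 ms = ms[c("MS_S", "MS_D", "MS_E")],
                 df = c(subjects = as.integer(a - 1), days = as.integer(a * (d - 1)),
                        residual = as.integer(a * d * (n - 1))),
                 dims = c(a = a, d = d, n = n),
                 variable_name = "exposure"),
            class = "varcomp")
}

# vectorized mean squares for a balanced (n, d, a) array
varcomp_ms <- function(y) {
  dm <- dim(y)
  n <- dm[1]; d <- dm[2]; a <- dm[3]
  day_means <- colMeans(y)                       # d x a
  subj_means <- colMeans(day_means)              # a
  grand <- mean(subj_means)
  c(mu = grand,
    MS_S = d * n * sum((subj_means - grand)^2) / (a - 1),
    MS_D = n * sum((day_means - rep(subj_means, each = d))^2) / (a * (d - 1)),
    MS_E = sum((y - rep(day_means, each = n))^2) / (a * d * (n - 1)))
}

#' @export
print.varcomp <- function(x, digits = 4, ...) {
  cat(sprintf("Balanced nested variance components ('%s'; %d subjects x %d days x %d minutes)\n",
              x$variable_name, x$dims["a"], x$dims["d"], x$dims["n"]))
  cat(sprintf("  mu     = %.*g\n", digits, x$mu))
  for (nm in names(x$components))
    cat(sprintf("  %s = %.*g%s\n", nm, digits, x$components[nm],
                if (x$raw[nm] < 0) sprintf(" (raw %.*g, clipped)", digits, x$raw[nm]) else ""))
  invisible(x)
}

#' @export
summary.varcomp <- function(object, ...) {
  tot <- sum(object$components)
  tab <- data.frame(
    component = c("between-subjects", "between-days", "within-day"),
    estimate = unname(object$components),
    raw = unname(object$raw),
    pct_of_total = if (tot > 0) 100 * unname(object$components) / tot else NA_real_,
    df = unname(object$df)
  )
  out <- list(mu = object$mu, table = tab, ms = object$ms, dims = object$dims)
  class(out) <- "summary.varcomp"
  out
}

#' @export
print.summary.varcomp <- function(x, ...) {
  cat(sprintf("mu = %.4g; mean squares: MS_S = %.4g, MS_D = %.4g, MS_E = %.4g\n",
              x$mu, x$ms["MS_S"], x$ms["MS_D"], x$ms["MS_E"]))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.varcomp <- function(object, ...) {
  c(mu = object$mu, object$components)
}

#' Simulate balanced data sets from a fitted variance-components model
#'
#' Draws new balanced parent data sets from the fitted Gaussian hierarchical
#' model with independent within-day errors (the fitted model carries no
#' autocorrelation information; use [generate_parent()] with a calibrated
#' profile for serially correlated data).
#'
#' @param object a `varcomp` fit.
#' @param nsim number of data sets.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of [parent_data()] of the fitted dimensions.
#' @export
simulate.varcomp <- function(object, nsim = 1, seed = 1L, ...) {
  prof <- posture_profile(object$variable_name, mu = object$mu,
                          var_bs = object$components[["var_bs"]],
                          var_bd = object$components[["var_bd"]],
                          var_wd = object$components[["var_wd"]],
                          acf_targets = NULL)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nsim)
  lapply(seeds, function(s)
    generate_parent(prof, n_subjects = object$dims[["a"]], n_days = object$dims[["d"]],
                    day_length = object$dims[["n"]], seed = s))
}

#' Mean within-day sample autocorrelation of a data set
#'
#' Computes, for each requested lag, the sample autocorrelation of every
#' subject-day series (mean-centered within the day, lag-0 sum of squares as
#' denominator) and averages it unweighted over all subject-days. Days with
#' zero variance are skipped with a warning.
#'
#' @param x a [parent_data()] or 3-d array `(minute, day, subject)`.
#' @param lags positive integer lags in minutes, each shorter than the day.
#' @return object of class `acf_estimate`: named numeric `acf` (per lag),
#'   `n_series` (days averaged).
#' @export
within_day_acf <- function(x, lags = c(1:5, 10)) {
  y <- unclass(x)
  stopifnot(is.array(y), length(dim(y)) == 3L)
  n <- dim(y)[1]
  stopifnot(all(lags >= 1), max(lags) < n)
  mat <- matrix(y, nrow = n)                      # one column per subject-day
  keep <- apply(mat, 2, stats::sd) > 0
  if (!all(keep))
    warning(sum(!keep), " zero-variance day(s) skipped in ACF averaging", call. = FALSE)
  mat <- mat[, keep, drop = FALSE]
  if (ncol(mat) == 0L) stop("no day with positive variance", call. = FALSE)
  lag_max <- max(lags)
  per_day <- apply(mat, 2, function(z)
    stats::acf(z, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[lags + 1L])
  if (length(lags) == 1L) per_day <- matrix(per_day, nrow = 1L)
  structure(list(acf = structure(rowMeans(per_day), names = as.character(lags)),
                 n_series = ncol(mat)),
            class = "acf_estimate")
}

#' @export
print.acf_estimate <- function(x, ...) {
  cat(sprintf("Mean within-day sample ACF over %d day series:\n", x$n_series))
  print(round(x$acf, 4))
  invisible(x)
}

#' Expected deflation of the sample variance of one autocorrelated block
#'
#' For a contiguous block of `n` observations from a stationary process with
#' autocorrelation `rho(k)`, the ordinary sample variance estimator is
#' biased downward:
#' \deqn{E[s^2]/\sigma^2 = 1 - \frac{2}{n(n-1)} \sum_{k=1}^{n-1} (n-k)\,\rho(k).}
#' This factor equals 1 under independence and shrinks as the block becomes
#' more autocorrelated — the mechanism behind the negative within-day
#' variance bias of sampling strategies that use large consecutive blocks.
#'
#' @param n block length (observations), `>= 2`.
#' @param acf the process autocorrelation: an `acf_mixture`, a
#'   [posture_profile()] (its calibrated mixture is used), or a numeric
#'   vector `rho(1), ..., rho(n-1)`.
#' @return the expectation ratio, a number in `(0, 1]` for nonnegative ACFs.
#' @examples
#' expected_block_variance_factor(2, c(0.5)) # 0.5
#' @export
expected_block_variance_factor <- function(n, acf) {
  if (n < 2) stop("block length must be at least 2", call. = FALSE)
  k <- seq_len(n - 1)
  rho <- if (inherits(acf, "posture_profile")) {
    mixture_acf(acf$mixture, k)
  } else if (inherits(acf, "acf_mixture") || (is.list(acf) && !is.null(acf$w))) {
    mixture_acf(acf, k)
  } else {
    acf <- as.numeric(acf)
    if (length(acf) < n - 1) stop("acf vector must cover lags 1..n-1", call. = FALSE)
    acf[k]
  }
  1 - (2 / (n * (n - 1))) * sum((n - k) * rho)
}
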