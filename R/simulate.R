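#' Draw one three-level block-bootstrap sample from a parent data set
#'
#' Implements the hierarchical resampling scheme for three-level data:
#' subjects are drawn *with* replacement (duplicates relabeled as distinct
#' levels before fitting, per standard non-parametric bootstrap practice),
#' then for every drawn subject `n_d` of the parent's days are drawn
#' *without* replacement, and within every selected day `q = t_tot / n_d`
#' minutes are taken *without* replacement as the union of contiguous blocks
#' laid out by the strategy's dispersion scheme (a fresh layout per selected
#' day). Sampled values are verbatim parent values; minutes are kept in time
#' order.
#'
#' Uses the current RNG state; see [run_strategy()] for seeded replication.
#'
#' @param parent a [parent_data()].
#' @param strategy a [sampling_strategy()].
#' @return a [parent_data()] of dimension `q` x `n_d` x `n_s` with subjects
#'   relabeled `B1, B2, ...`.
#' @export
draw_bootstrap_sample <- function(parent, strategy) {
  stopifnot(inherits(parent, "parent_data"), inherits(strategy, "sampling_strategy"))
  y <- draw_bootstrap_array(unclass(parent), strategy)
  parent_data(y, variable_name = attr(parent, "variable_name"),
              subjects = paste0("B", seq_len(dim(y)[3])))
}

# fast path: returns the bare (q, n_d, n_s) array
draw_bootstrap_array <- function(P, strategy) {
  dm <- dim(P)
  L <- dm[1]; D <- dm[2]; A <- dm[3]
  n_s <- strategy$n_s; n_d <- strategy$n_d
  q <- strategy$q; t_b <- strategy$t_b; nb <- strategy$n_blocks
  if (n_d > D) stop("strategy asks for more days than the parent holds", call. = FALSE)
  if (q > L) stop("strategy asks for more minutes per day than the parent holds", call. = FALSE)
  subj <- sample.int(A, n_s, replace = TRUE)
  days <- vapply(seq_len(n_s), function(i) sample.int(D, n_d), integer(n_d))
  days <- matrix(days, nrow = n_d)                          # n_d x n_s
  cells <- n_d * n_s
  if (strategy$dispersion == "random") {
    slack <- L - nb * t_b
    draws <- matrix(sample.int(slack + 1L, nb * cells, replace = TRUE) - 1L, nrow = nb)
    if (nb > 1L) draws <- apply(draws, 2L, sort)
    starts <- draws + (seq_len(nb) - 1L) * t_b              # nb x cells
  } else {
    g <- (L - nb * t_b) %/% nb
    s0 <- sample.int(g + 1L, cells, replace = TRUE) - 1L
    starts <- outer((seq_len(nb) - 1L) * (g + t_b), s0, `+`)
  }
  # minute indices per cell (q x cells), 1-based, in time order
  mins <- apply(starts, 2L, function(st) blocks_to_minutes(st, t_b)) + 1L
  mins <- matrix(mins, nrow = q)
  cell_off <- L * (rep(days, times = 1L) - 1L) + L * D * (rep(subj, each = n_d) - 1L)
  idx <- mins + rep(cell_off, each = q)
  array(P[idx], c(q, n_d, n_s))
}

#' Bias of a set of estimates against the parent truth
#'
#' Accuracy of a sampling strategy is the mean of the bootstrap estimates
#' minus the "true" value from the parent data set, so that under-estimation
#' shows up as a negative bias.
#'
#' @param estimates numeric vector of bootstrap estimates.
#' @param truth true value from the parent fit.
#' @return `mean(estimates) - truth`.
#' @export
bias <- function(estimates, truth) {
  if (!length(estimates)) stop("no estimates", call. = FALSE)
  mean(estimates) - truth
}

#' Percentile prediction interval relative to the parent truth
#'
#' The precision of a strategy is summarized by the empirical 5th and 95th
#' percentiles (for `level = 90`) of the bootstrap estimates, reported
#' relative to the true value. Percentiles use the nearest-rank rule (order
#' statistic `ceiling(p * n)`); with thousands of replicates the choice
#' among percentile definitions is immaterial beyond Monte-Carlo noise.
#'
#' @param estimates numeric vector of bootstrap estimates (`>= 20`).
#' @param truth true value from the parent fit.
#' @param level interval coverage in percent.
#' @return named numeric `c(low, high)`, each percentile minus `truth`.
#' @examples
#' prediction_interval(0:100 / 100, truth = 0)
#' @export
prediction_interval <- function(estimates, truth, level = 90) {
  n <- length(estimates)
  if (n < 20L) stop("need at least 20 estimates for a prediction interval", call. = FALSE)
  stopifnot(level > 0, level < 100)
  p <- c((100 - level) / 200, 1 - (100 - level) / 200)
  s <- sort(estimates)
  q <- s[pmax(1L, ceiling(p * n))]
  c(low = unname(q[1] - truth), high = unname(q[2] - truth))
}

#' Simulate one sampling strategy by bootstrap
#'
#' Runs `n_reps` three-level block-bootstrap draws from the parent under the
#' given strategy, estimates the variance components of every draw with
#' [estimate_varcomp()] (clipped at zero), and summarizes each component's
#' accuracy ([bias()]) and precision ([prediction_interval()]) against the
#' parent's full-data estimates.
#'
#' @param parent a [parent_data()].
#' @param strategy a [sampling_strategy()].
#' @param n_reps bootstrap replicates (the full study design uses 5000; the
#'   default here is a scaled-down 500).
#' @param seed integer seed; results are reproducible given the seed.
#' @param level prediction-interval coverage, percent.
#' @param keep_estimates keep the full `n_reps` x 4 matrix of estimates.
#' @return object of class `strategy_result`: `strategy`, `truth`
#'   (named vector from the parent fit), `n_reps`, `seed`, `table` (one row
#'   per component: bias, pi_low, pi_high, mean_estimate, truth),
#'   `percentiles` (1..99 per component), and optionally `estimates`.
#' @export
run_strategy <- function(parent, strategy, n_reps = 500L, seed = 1L, level = 90,
                         keep_estimates = FALSE) {
  stopifnot(inherits(parent, "parent_data"), inherits(strategy, "sampling_strategy"))
  truth_fit <- estimate_varcomp(parent)
  truth <- coef(truth_fit)
  P <- unclass(parent)
  set.seed(seed)
  est <- matrix(NA_real_, n_reps, 4L,
                dimnames = list(NULL, c("mu", "var_bs", "var_bd", "var_wd")))
  for (r in seq_len(n_reps)) {
    y <- draw_bootstrap_array(P, strategy)
    ms <- varcomp_ms(y)
    n <- strategy$q; d <- strategy$n_d
    est[r, ] <- c(ms[["mu"]],
                  max((ms[["MS_S"]] - ms[["MS_D"]]) / (d * n), 0),
                  max((ms[["MS_D"]] - ms[["MS_E"]]) / n, 0),
                  ms[["MS_E"]])
  }
  comp <- c("var_bs", "var_bd", "var_wd")
  tab <- do.call(rbind, lapply(comp, function(cc) {
    pi <- prediction_interval(est[, cc], truth[cc], level = level)
    data.frame(component = sub("var_", "", cc),
               bias = bias(est[, cc], truth[cc]),
               pi_low = pi[["low"]], pi_high = pi[["high"]],
               mean_estimate = mean(est[, cc]), truth = unname(truth[cc]))
  }))
  rownames(tab) <- NULL
  pctl <- apply(est[, comp, drop = FALSE], 2L,
                function(v) sort(v)[pmax(1L, ceiling(1:99 / 100 * n_reps))])
  out <- list(strategy = strategy, truth = truth, n_reps = as.integer(n_reps),
              seed = as.integer(seed), level = level, table = tab,
              percentiles = pctl,
              variable_name = attr(parent, "variable_name"))
  if (keep_estimates) out$estimates <- est
  structure(out, class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, digits = 3, ...) {
  s <- x$strategy
  cat(sprintf("Bootstrap result ('%s', %d reps, seed %d): n_s=%d t_tot=%d n_d=%d t_b=%d %s\n",
              x$variable_name, x$n_reps, x$seed, s$n_s, s$t_tot, s$n_d, s$t_b, s$dispersion))
  tab <- x$table
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-3s bias %+.*g  %d%% PI [%.*g, %.*g]  (truth %.*g)\n",
                tab$component[i], digits, tab$bias[i], x$level,
                digits, tab$pi_low[i], digits, tab$pi_high[i], digits, tab$truth[i]))
  invisible(x)
}

#' Simulate a full grid of strategies and exposure variables
#'
#' Crosses every strategy in a [enumerate_strategies()] set with every
#' parent data set (one per exposure variable) and runs [run_strategy()] on
#' each cell with an independent child seed derived from the master seed, so
#' any execution order yields the identical report. Cell failures are
#' recorded (as `NA` rows) and the run continues.
#'
#' @param parents a [parent_data()] or a named list of them (names = exposure
#'   variables).
#' @param strategies a `strategy_set` from [enumerate_strategies()] (or a
#'   data.frame with the same columns).
#' @param n_reps bootstrap replicates per cell.
#' @param seed master seed.
#' @param level prediction-interval coverage, percent.
#' @return object of class `simulation_report`; its `table` holds one row
#'   per (variable, strategy, component) with columns `variable`, `n_s`,
#'   `t_tot`, `n_d`, `t_b`, `dispersion`, `component`, `bias`, `pi_low`,
#'   `pi_high`, `mean_estimate`, `truth`, `n_reps`.
#' @export
run_grid <- function(parents, strategies, n_reps = 500L, seed = 1L, level = 90) {
  if (inherits(parents, "parent_data")) {
    parents <- stats::setNames(list(parents), attr(parents, "variable_name"))
  }
  stopifnot(is.list(parents), length(parents) >= 1)
  if (is.null(names(parents)))
    names(parents) <- vapply(parents, attr, "", "variable_name")
  if (!nrow(strategies)) {
    warning("empty strategy list; empty report", call. = FALSE)
    return(structure(list(table = data.frame(), n_reps = n_reps, seed = seed),
                     class = "simulation_report"))
  }
  day_length <- attr(strategies, "day_length")
  if (is.null(day_length)) day_length <- dim(parents[[1]])[1]
  set.seed(seed)
  child_seeds <- matrix(sample.int(.Machine$integer.max, nrow(strategies) * length(parents)),
                        nrow(strategies), length(parents))
  rows <- vector("list", nrow(strategies) * length(parents))
  k <- 0L
  for (v in seq_along(parents)) {
    for (i in seq_len(nrow(strategies))) {
      k <- k + 1L
      srow <- strategies[i, , drop = FALSE]
      rows[[k]] <- tryCatch({
        st <- strategy_from_row(srow, day_length)
        res <- run_strategy(parents[[v]], st, n_reps = n_reps,
                            seed = child_seeds[i, v], level = level)
        cbind(data.frame(variable = names(parents)[v], n_s = st$n_s, t_tot = st$t_tot,
                         n_d = st$n_d, t_b = st$t_b, dispersion = st$dispersion),
              res$table, n_reps = res$n_reps)
      }, error = function(e) {
        warning(sprintf("cell (%s; n_s=%d t_tot=%d n_d=%d t_b=%d %s) failed: %s",
                        names(parents)[v], srow$n_s, srow$t_tot, srow$n_d, srow$t_b,
                        srow$dispersion, conditionMessage(e)), call. = FALSE)
        cbind(data.frame(variable = names(parents)[v], n_s = srow$n_s, t_tot = srow$t_tot,
                         n_d = srow$n_d, t_b = srow$t_b, dispersion = srow$dispersion),
              data.frame(component = c("bs", "bd", "wd"), bias = NA_real_,
                         pi_low = NA_real_, pi_high = NA_real_,
                         mean_estimate = NA_real_, truth = NA_real_),
              n_reps = n_reps)
      })
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, n_reps = as.integer(n_reps), seed = as.integer(seed),
                 level = level,
                 parents = lapply(parents, function(p) coef(estimate_varcomp(p))),
                 config = list(n_strategies = nrow(strategies),
                               variables = names(parents), day_length = day_length)),
            class = "simulation_report")
}

#' @export
print.simulation_report <- function(x, ...) {
  cat(sprintf("Simulation report: %d strategies x %d variable(s), %d reps each (seed %d)\n",
              x$config$n_strategies, length(x$config$variables), x$n_reps, x$seed))
  cat(sprintf("  %d result rows; variables: %s\n", nrow(x$table),
              paste(x$config$variables, collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.simulation_report <- function(x, ...) x$table

#' Write a simulation report table to CSV
#'
#' @param report a `simulation_report` from [run_grid()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "simulation_report"))
  utils::write.csv(report$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
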