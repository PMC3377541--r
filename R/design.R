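#' Construct a sampling strategy
#'
#' A sampling strategy prescribes one simulated measurement campaign:
#' `n_s` subjects, `t_tot` total minutes per subject spread evenly over
#' `n_d` days, collected within each day in contiguous blocks of `t_b`
#' minutes dispersed either at `"random"` (uniform non-overlapping
#' placement) or at a `"fixed"` interval (an evenly spaced comb with a
#' random offset).
#'
#' Feasibility requires `n_d` to divide `t_tot`, the per-day time
#' `q = t_tot / n_d` to be a multiple of `t_b` with `t_b <= q`, and
#' `q <= day_length`.
#'
#' @param n_s subjects sampled.
#' @param t_tot total sampling time per subject, minutes.
#' @param n_d days per subject.
#' @param t_b block size, minutes.
#' @param dispersion `"random"` or `"fixed"`.
#' @param day_length working-day length, minutes.
#' @return list of class `sampling_strategy` with the five parameters plus
#'   the derived `q` (minutes per day) and `n_blocks` (blocks per day).
#' @examples
#' sampling_strategy(10, 120, 2, 15, "random")
#' @export
sampling_strategy <- function(n_s, t_tot, n_d, t_b, dispersion = c("random", "fixed"),
                              day_length = 480L) {
  dispersion <- match.arg(dispersion)
  stopifnot(n_s >= 1, t_tot >= 1, n_d >= 1, t_b >= 1)
  if (t_tot %% n_d != 0)
    stop("n_d must divide t_tot", call. = FALSE)
  q <- t_tot %/% n_d
  if (t_b > q) stop("block size t_b cannot exceed the sampling time per day", call. = FALSE)
  if (q %% t_b != 0) stop("t_b must divide the sampling time per day", call. = FALSE)
  if (q > day_length) stop("sampling time per day exceeds the day length", call. = FALSE)
  structure(list(n_s = as.integer(n_s), t_tot = as.integer(t_tot),
                 n_d = as.integer(n_d), t_b = as.integer(t_b),
                 dispersion = dispersion, day_length = as.integer(day_length),
                 q = as.integer(q), n_blocks = as.integer(q %/% t_b)),
            class = "sampling_strategy")
}

#' @export
print.sampling_strategy <- function(x, ...) {
  cat(sprintf("Sampling strategy: n_s = %d, t_tot = %d min, n_d = %d, t_b = %d min, %s dispersion\n",
              x$n_s, x$t_tot, x$n_d, x$t_b, x$dispersion))
  cat(sprintf("  %d min/day in %d block(s), day length %d min\n", x$q, x$n_blocks, x$day_length))
  invisible(x)
}

#' Enumerate feasible, non-redundant sampling strategies
#'
#' Expands the full Cartesian product of the parameter value sets and drops
#' (i) infeasible combinations — block size exceeding the per-day sampling
#' time, per-day time not a multiple of the block size, or exceeding the day
#' length — and (ii) redundant fixed-interval entries with a single block
#' per day, which coincide exactly with the corresponding random strategy.
#' For the study grid (`n_s` 10/20; `t_tot` 60/120/240/480; `n_d` 2/4;
#' `t_b` 1/15/60/240; both dispersions) this reduces 128 combinations to 80
#' strategies. Ordering is deterministic (lexicographic in `n_s`, `t_tot`,
#' `n_d`, `t_b`, dispersion).
#'
#' @param n_s,t_tot,n_d,t_b value sets (non-empty numeric vectors); defaults
#'   are the study grid.
#' @param dispersion subset of `c("random", "fixed")`.
#' @param day_length working-day length, minutes.
#' @return data.frame of class `strategy_set` with columns `n_s`, `t_tot`,
#'   `n_d`, `t_b`, `dispersion`, `q`, `n_blocks`, one row per strategy;
#'   attribute `n_combinations` records the size of the unpruned product.
#' @examples
#' nrow(enumerate_strategies()) # 80
#' @export
enumerate_strategies <- function(n_s = c(10L, 20L), t_tot = c(60L, 120L, 240L, 480L),
                                 n_d = c(2L, 4L), t_b = c(1L, 15L, 60L, 240L),
                                 dispersion = c("random", "fixed"),
                                 day_length = 480L) {
  if (!length(n_s) || !length(t_tot) || !length(n_d) || !length(t_b) || !length(dispersion))
    stop("all parameter value sets must be non-empty", call. = FALSE)
  dispersion <- match.arg(dispersion, several.ok = TRUE)
  g <- expand.grid(dispersion = dispersion, t_b = sort(t_b), n_d = sort(n_d),
                   t_tot = sort(t_tot), n_s = sort(n_s),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("n_s", "t_tot", "n_d", "t_b", "dispersion")]
  feasible <- g$t_tot %% g$n_d == 0
  q <- ifelse(feasible, g$t_tot %/% g$n_d, NA_integer_)
  feasible <- feasible & !is.na(q) & g$t_b <= q & q %% g$t_b == 0 & q <= day_length
  redundant <- feasible & g$dispersion == "fixed" & q == g$t_b
  keep <- feasible & !redundant
  out <- g[keep, , drop = FALSE]
  out$q <- as.integer(q[keep])
  out$n_blocks <- as.integer(out$q %/% out$t_b)
  o <- order(out$n_s, out$t_tot, out$n_d, out$t_b, out$dispersion)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_combinations") <- nrow(g)
  attr(out, "day_length") <- as.integer(day_length)
  class(out) <- c("strategy_set", "data.frame")
  out
}

# one row of a strategy_set -> sampling_strategy
strategy_from_row <- function(row, day_length) {
  sampling_strategy(row$n_s, row$t_tot, row$n_d, row$t_b, row$dispersion,
                    day_length = day_length)
}

#' Place sampling blocks within one working day
#'
#' `place_blocks_random` draws a uniformly distributed non-overlapping
#' placement of `n_blocks` blocks of `t_b` minutes: `n_blocks` integers are
#' drawn uniformly with replacement from `0..(day_length - n_blocks * t_b)`,
#' sorted, and the k-th (0-based) is shifted by `k * t_b`. This makes every
#' non-overlapping integer-minute layout equally likely; for `t_b = 1` it is
#' equivalent to simple random sampling of minutes without replacement.
#'
#' `place_blocks_fixed` spaces the blocks evenly: with gap
#' `g = (day_length - n_blocks * t_b) / n_blocks`, the first start is drawn
#' uniformly from the integer minutes `0..g` and successive starts follow at
#' intervals of `g + t_b`. (If a user-supplied grid makes `g` non-integer it
#' is floored, leaving the leftover slack after the last block.) With a
#' single block both schemes coincide.
#'
#' Both functions use the current RNG state.
#'
#' @param day_length day length, minutes.
#' @param n_blocks number of blocks.
#' @param t_b block size, minutes.
#' @return integer vector of 0-based block start minutes, strictly
#'   increasing, each block fitting inside the day without overlap.
#' @examples
#' set.seed(1)
#' place_blocks_fixed(480, 4, 15) # comb with spacing 120
#' @export
place_blocks_random <- function(day_length, n_blocks, t_b) {
  check_capacity(day_length, n_blocks, t_b)
  n_blocks <- as.integer(n_blocks); t_b <- as.integer(t_b)
  slack <- as.integer(day_length) - n_blocks * t_b
  draws <- sort(sample.int(slack + 1L, n_blocks, replace = TRUE) - 1L)
  draws + (seq_len(n_blocks) - 1L) * t_b
}

#' @rdname place_blocks_random
#' @export
place_blocks_fixed <- function(day_length, n_blocks, t_b) {
  check_capacity(day_length, n_blocks, t_b)
  n_blocks <- as.integer(n_blocks); t_b <- as.integer(t_b)
  g <- (as.integer(day_length) - n_blocks * t_b) %/% n_blocks
  s <- sample.int(g + 1L, 1L) - 1L
  s + (seq_len(n_blocks) - 1L) * (g + t_b)
}

check_capacity <- function(day_length, n_blocks, t_b) {
  stopifnot(n_blocks >= 1, t_b >= 1)
  if (n_blocks * t_b > day_length)
    stop("blocks do not fit in the day: n_blocks * t_b > day_length", call. = FALSE)
  invisible(TRUE)
}

# 0-based minute indices covered by a block layout
blocks_to_minutes <- function(starts, t_b) {
  as.integer(outer(seq_len(t_b) - 1L, starts, `+`))
}
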