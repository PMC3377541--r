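#' Map inclinometer interval codes to central angles
#'
#' Codes 1-6 denote 15-degree elevation intervals from 0 to 90 degrees and
#' are replaced by the central angle of the interval; code 7 (above 90
#' degrees) is assigned 105 degrees.
#'
#' @param code integer vector of codes in `1..7`.
#' @return numeric vector of degrees.
#' @examples
#' category_to_angle(c(1, 4, 7)) # 7.5, 52.5, 105
#' @export
category_to_angle <- function(code) {
  if (anyNA(code) || any(code < 1 | code > 7 | code != as.integer(code)))
    stop("codes must be integers in 1..7 with no missing values", call. = FALSE)
  ifelse(code == 7, 105, 15 * (code - 1) + 7.5)
}

#' Minute-level exposure summaries from 60 seconds of interval codes
#'
#' Computes the three exposure variables for one minute: average elevation
#' (mean of the central angles, degrees), percentage of time above 90 degrees
#' (share of code 7) and percentage of time below 15 degrees (share of
#' code 1). A minute containing any missing second is flagged wholly missing
#' (`NA` in all three variables) and left for [interpolate_missing()].
#'
#' @param codes integer vector of exactly 60 codes (`NA` allowed = missing).
#' @return named numeric vector `avg_elevation`, `pct_above_90`,
#'   `pct_below_15`.
#' @examples
#' minute_summaries(rep(7L, 60))
#' @export
minute_summaries <- function(codes) {
  if (length(codes) != 60L) stop("a minute is exactly 60 one-second codes", call. = FALSE)
  if (anyNA(codes))
    return(c(avg_elevation = NA_real_, pct_above_90 = NA_real_, pct_below_15 = NA_real_))
  ang <- category_to_angle(codes)
  c(avg_elevation = mean(ang),
    pct_above_90 = 100 * sum(codes == 7) / 60,
    pct_below_15 = 100 * sum(codes == 1) / 60)
}

#' Convert a 1-Hz code stream to minute-level exposure series
#'
#' Splits the stream into consecutive whole minutes (a trailing partial
#' minute is dropped) and applies [minute_summaries()] to each.
#'
#' @param codes integer vector of 1-Hz codes (`NA` = missing).
#' @return data.frame with columns `minute` (0-based), `avg_elevation`,
#'   `pct_above_90`, `pct_below_15`; missing minutes hold `NA`.
#' @export
abduflex_to_minutes <- function(codes) {
  n_min <- length(codes) %/% 60L
  if (n_min < 1L) stop("stream shorter than one minute", call. = FALSE)
  m <- matrix(codes[seq_len(60L * n_min)], nrow = 60L)
  out <- t(apply(m, 2L, minute_summaries))
  data.frame(minute = seq_len(n_min) - 1L, out, row.names = NULL)
}

#' Repair short missing segments by linear interpolation
#'
#' Interior runs of missing minutes no longer than `max_gap` are replaced by
#' linear interpolation between the flanking observed values; missing runs at
#' the start or end of the series are filled by nearest-value extension.
#' Longer interior gaps are an error (reported with their position), so
#' silent repair of substantial data loss cannot occur.
#'
#' @param values numeric vector of minute values with `NA` for missing.
#' @param max_gap largest interior gap (minutes) that may be interpolated.
#' @return numeric vector without missing values.
#' @examples
#' interpolate_missing(c(10, NA, 20))        # 10 15 20
#' interpolate_missing(c(0, NA, NA, 30))     # 0 10 20 30
#' @export
interpolate_missing <- function(values, max_gap = 30L) {
  if (!anyNA(values)) return(values)
  if (all(is.na(values))) stop("series is entirely missing", call. = FALSE)
  r <- rle(is.na(values))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  interior <- r$values & starts > 1L & ends < length(values)
  too_long <- interior & r$lengths > max_gap
  if (any(too_long)) {
    i <- which(too_long)[1L]
    stop(sprintf("missing run of %d minutes starting at minute %d exceeds max_gap = %d",
                 r$lengths[i], starts[i], max_gap), call. = FALSE)
  }
  obs <- which(!is.na(values))
  out <- stats::approx(obs, values[obs], xout = seq_along(values),
                       method = "linear", rule = 2)$y
  out
}

#' Read a 1-Hz inclinometer recording from CSV
#'
#' Expected header: `subject,day,second,code`, codes `1..7` or empty for
#' missing seconds.
#'
#' @param path file path.
#' @return data.frame with one row per (subject, day) and a list-column
#'   `codes` holding each recording's integer code stream in second order.
#' @export
read_abduflex_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "day", "second", "code")
  if (!all(need %in% names(df)))
    stop("recording CSV must have columns subject, day, second, code", call. = FALSE)
  ok <- is.na(df$code) | (df$code >= 1 & df$code <= 7)
  if (!all(ok)) stop("codes must be in 1..7 or empty", call. = FALSE)
  df <- df[order(df$subject, df$day, df$second), ]
  sp <- split(as.integer(df$code), paste(df$subject, df$day, sep = "\r"))
  key <- do.call(rbind, strsplit(names(sp), "\r", fixed = TRUE))
  out <- data.frame(subject = key[, 1], day = key[, 2], row.names = NULL)
  out$codes <- unname(sp)
  out[order(out$subject, out$day), , drop = FALSE]
}
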