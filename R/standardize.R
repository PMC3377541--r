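#' Pad a short working day to a fixed length by within-day block bootstrap
#'
#' Days shorter than `target` minutes are extended by repeatedly appending a
#' contiguous block of `block` minutes resampled from the *original*
#' (pre-padding) data of the same day — the block start is drawn uniformly
#' over all starts admitting a full block, with replacement across draws —
#' until at least `target` minutes are present; the result is then truncated
#' to exactly `target`. Days longer than `target` are truncated. Uses the
#' current RNG state; seed the session (or use [standardize_dataset()]) for
#' reproducibility.
#'
#' @param values numeric vector of minute values for one day (no missing
#'   values; repair gaps first with [interpolate_missing()]).
#' @param target day length to standardize to, minutes.
#' @param block padding block length, minutes.
#' @return numeric vector of length `target`.
#' @examples
#' set.seed(1)
#' length(pad_day(rnorm(337))) # 480
#' @export
pad_day <- function(values, target = 480L, block = 30L) {
  if (anyNA(values)) stop("day contains missing values; interpolate first", call. = FALSE)
  n0 <- length(values)
  if (n0 >= target) return(values[seq_len(target)])
  if (n0 < block)
    stop(sprintf("day has only %d minutes, shorter than the padding block (%d)", n0, block),
         call. = FALSE)
  out <- values
  while (length(out) < target) {
    start <- sample.int(n0 - block + 1L, 1L)
    out <- c(out, values[start:(start + block - 1L)])
  }
  out[seq_len(target)]
}

#' Assemble a balanced parent data set from minute-level day series
#'
#' Takes a long-format table of minute values (one row per recorded minute)
#' and produces a fully balanced [parent_data()]: each subject contributes
#' exactly `n_days` days (subjects with more days have the required number
#' selected uniformly at random; subjects with fewer are an error) and each
#' day exactly `target` minutes via [pad_day()].
#'
#' @param x data.frame with columns `subject`, `day`, `minute`, `value`.
#' @param n_days days per subject to retain; default: the minimum number of
#'   days available across subjects.
#' @param target,block passed to [pad_day()].
#' @param seed integer seed for day selection and padding.
#' @param variable_name label for the resulting data set.
#' @return a [parent_data()] of dimension `target` x `n_days` x n-subjects.
#' @export
standardize_dataset <- function(x, n_days = NULL, target = 480L, block = 30L,
                                seed = 1L, variable_name = "exposure") {
  need <- c("subject", "day", "minute", "value")
  if (!all(need %in% names(x)))
    stop("x must have columns subject, day, minute, value", call. = FALSE)
  set.seed(seed)
  subjects <- unique(x$subject)
  days_by_subject <- lapply(subjects, function(s) unique(x$day[x$subject == s]))
  if (is.null(n_days)) n_days <- min(lengths(days_by_subject))
  short <- subjects[lengths(days_by_subject) < n_days]
  if (length(short))
    stop("subjects with fewer than ", n_days, " days: ",
         paste(short, collapse = ", "), call. = FALSE)
  y <- array(0, c(target, n_days, length(subjects)))
  for (i in seq_along(subjects)) {
    dd <- days_by_subject[[i]]
    if (length(dd) > n_days) dd <- dd[sort(sample.int(length(dd), n_days))]
    for (j in seq_len(n_days)) {
      rows <- x$subject == subjects[i] & x$day == dd[j]
      v <- x$value[rows][order(x$minute[rows])]
      y[, j, i] <- tryCatch(pad_day(v, target = target, block = block),
                            error = function(e) stop("subject ", subjects[i], ", day ",
                                                     dd[j], ": ", conditionMessage(e),
                                                     call. = FALSE))
    }
  }
  parent_data(y, variable_name = variable_name, subjects = subjects)
}
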