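#' Balanced parent exposure data set
#'
#' A parent data set is the fixed, fully balanced universe of minute-level
#' exposure values from which simulated measurement campaigns are resampled:
#' `day_length` minutes per day, the same number of days per subject, for
#' every subject. Values are stored as a numeric array with dimensions
#' `(minute, day, subject)`.
#'
#' @param values numeric array, `dim = c(day_length, n_days, n_subjects)`,
#'   all values finite.
#' @param variable_name label of the exposure variable.
#' @param subjects optional subject labels (length `n_subjects`).
#' @return object of class `parent_data`.
#' @examples
#' pd <- parent_data(array(rnorm(2 * 2 * 5), c(5, 2, 2)), "toy")
#' dim(pd)
#' @export
parent_data <- function(values, variable_name = "exposure", subjects = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3-d array (minute, day, subject)", call. = FALSE)
  if (!all(is.finite(values))) stop("all parent values must be finite", call. = FALSE)
  d <- dim(values)
  if (is.null(subjects)) subjects <- paste0("S", seq_len(d[3]))
  stopifnot(length(subjects) == d[3])
  structure(values, variable_name = variable_name, subjects = as.character(subjects),
            class = "parent_data")
}

#' @export
print.parent_data <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("Parent exposure data set '%s': %d subjects x %d days x %d minutes (%d values)\n",
              attr(x, "variable_name"), d[3], d[2], d[1], length(x)))
  cat(sprintf("  range [%.3g, %.3g], grand mean %.4g\n", min(x), max(x), mean(x)))
  invisible(x)
}

#' @export
summary.parent_data <- function(object, ...) {
  fit <- estimate_varcomp(object)
  cat("Balanced parent data set; full-data variance component estimates:\n\n")
  print(fit)
  invisible(fit)
}

n_subjects <- function(x) dim(x)[3]
n_days <- function(x) dim(x)[2]
day_length_of <- function(x) dim(x)[1]

#' @export
as.data.frame.parent_data <- function(x, ...) {
  d <- dim(x)
  data.frame(
    subject = rep(attr(x, "subjects"), each = d[1] * d[2]),
    day = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    minute = rep(seq_len(d[1]) - 1L, times = d[2] * d[3]),
    value = as.numeric(x)
  )
}

#' Read and write parent data as long-format CSV
#'
#' The on-disk dialect is a long table with header `subject,day,minute,value`,
#' one row per minute, minutes 0-based within each day. `read_parent_csv`
#' requires the table to be balanced.
#'
#' @param path file path.
#' @param variable_name label attached to the data set on read.
#' @return `read_parent_csv` returns a [parent_data()]; `write_parent_csv`
#'   returns `path` invisibly.
#' @export
read_parent_csv <- function(path, variable_name = "exposure") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "day", "minute", "value")
  if (!all(need %in% names(df)))
    stop("parent CSV must have columns subject, day, minute, value", call. = FALSE)
  long_to_parent(df, variable_name)
}

long_to_parent <- function(df, variable_name = "exposure") {
  subjects <- unique(df$subject)
  days <- sort(unique(df$day))
  n_min <- length(unique(df$minute))
  if (nrow(df) != length(subjects) * length(days) * n_min)
    stop("parent table is not balanced", call. = FALSE)
  o <- order(match(df$subject, subjects), df$day, df$minute)
  counts <- table(df$subject, df$day)
  if (length(unique(as.integer(counts))) != 1L)
    stop("parent table is not balanced", call. = FALSE)
  parent_data(array(df$value[o], c(n_min, length(days), length(subjects))),
              variable_name = variable_name, subjects = subjects)
}

#' @rdname read_parent_csv
#' @param x a [parent_data()].
#' @export
write_parent_csv <- function(x, path) {
  stopifnot(inherits(x, "parent_data"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
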