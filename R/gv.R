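#' Conventional glycemic-variability metrics
#'
#' Mean glucose, sample standard deviation (n-1 denominator), coefficient
#' of variation (%CV = 100 * SD / mean) and time in the target range,
#' computed over the full supplied window.
#'
#' @param series A [glucose_series()] or numeric vector (mmol/l).
#' @param range_low,range_high Target-range bounds, mmol/l; both inclusive.
#'   Default 3.9-8.9, the band commonly taken as acceptable in clinical
#'   practice.
#' @return A list of class `gv_metrics`: `mean_glucose`, `sd`,
#'   `cv_percent`, `tir_hours_per_day`, `n_total`, `n_in_range`,
#'   `range_low`, `range_high`.
#' @examples
#' compute_gv(c(4, 6))$cv_percent  # 28.28
#' @export
compute_gv <- function(series, range_low = 3.9, range_high = 8.9) {
  v <- series_values(series)
  if (length(v) < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(v)
  if (m <= 0) stop("non-positive mean glucose", call. = FALSE)
  s <- sd(v)
  n_in <- sum(v >= range_low & v <= range_high)
  structure(list(
    mean_glucose = m, sd = s, cv_percent = 100 * s / m,
    tir_hours_per_day = 24 * n_in / length(v),
    n_total = length(v), n_in_range = n_in,
    range_low = range_low, range_high = range_high
  ), class = "gv_metrics")
}

#' Time in target range
#'
#' Hours per day with glucose inside `[low, high]` (closed interval):
#' `24 * n_in_range / n_total`.
#'
#' @inheritParams compute_gv
#' @param low,high Range bounds, mmol/l, `low < high`; both inclusive.
#' @return Hours per day, in `[0, 24]`.
#' @export
time_in_range <- function(series, low = 3.9, high = 8.9) {
  stopifnot(low < high)
  v <- series_values(series)
  if (!length(v)) stop("empty series", call. = FALSE)
  24 * sum(v >= low & v <= high) / length(v)
}

#' @export
print.gv_metrics <- function(x, ...) {
  cat(sprintf(
    "<gv_metrics> mean %.2f mmol/l, SD %.2f, CV %.1f%%, TIR %.1f h/day (%d/%d in [%g, %g])\n",
    x$mean_glucose, x$sd, x$cv_percent, x$tir_hours_per_day,
    x$n_in_range, x$n_total, x$range_low, x$range_high))
  invisible(x)
}
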