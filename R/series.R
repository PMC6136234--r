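#' Construct a glucose series object
#'
#' A `glucose_series` holds one subject's uniformly sampled CGM trace:
#' glucose concentrations in mmol/l at a fixed sampling interval, plus
#' identifying fields and free-form metadata (QC flags, clipping fraction,
#' interpolated indices).
#'
#' @param values Numeric vector of glucose concentrations (mmol/l); all
#'   finite and positive, length at least 2.
#' @param interval_min Sampling interval in minutes (default 5, the common
#'   CGM sensor rate).
#' @param subject_id Opaque subject identifier.
#' @param t0 Optional start timestamp, ISO-8601 string or `POSIXct`. When
#'   absent a nominal grid starting at `"2000-01-01T00:00:00"` is assumed
#'   and recorded in `meta$nominal_t0`.
#' @param group Optional group label (e.g. `"ND"`, `"T2D"`, `"T1D"`).
#' @param meta Named list of annotations.
#'
#' @return An object of class `glucose_series`.
#' @examples
#' gs <- glucose_series(c(5.1, 5.3, 5.6, 5.4), interval_min = 5)
#' gs
#' @export
glucose_series <- function(values, interval_min = 5, subject_id = "anon",
                           t0 = NULL, group = NULL, meta = list()) {
  values <- as.numeric(values)
  if (length(values) < 2) {
    stop("a glucose series needs at least 2 values", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("glucose values must all be finite", call. = FALSE)
  }
  if (any(values <= 0)) {
    stop("glucose values must be positive (mmol/l)", call. = FALSE)
  }
  if (!is.numeric(interval_min) || length(interval_min) != 1 ||
      interval_min <= 0) {
    stop("interval_min must be a single positive number", call. = FALSE)
  }
  if (is.null(t0)) {
    meta$nominal_t0 <- TRUE
    t0 <- "2000-01-01T00:00:00"
  }
  if (inherits(t0, "POSIXct")) {
    t0 <- format(t0, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  }
  structure(
    list(subject_id = as.character(subject_id), t0 = t0,
         interval_min = interval_min, values = values,
         group = if (is.null(group)) NA_character_ else as.character(group),
         meta = meta),
    class = "glucose_series"
  )
}

#' @export
print.glucose_series <- function(x, ...) {
  dur_h <- length(x$values) * x$interval_min / 60
  cat(sprintf("<glucose_series> subject %s%s: %d samples @ %g min (%.1f h)\n",
              x$subject_id,
              if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              length(x$values), x$interval_min, dur_h))
  cat(sprintf("  mean %.2f mmol/l, range %.2f-%.2f\n",
              mean(x$values), min(x$values), max(x$values)))
  flags <- names(x$meta)
  if (length(flags)) cat("  meta:", paste(flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.glucose_series <- function(x) length(x$values)

#' Coerce to a glucose series
#'
#' Numeric vectors are wrapped with a nominal 5-min grid; existing
#' `glucose_series` objects pass through unchanged.
#'
#' @param x A numeric vector or `glucose_series`.
#' @param interval_min Sampling interval used when wrapping a bare vector.
#' @return A `glucose_series`.
#' @export
as_glucose_series <- function(x, interval_min = 5) {
  if (inherits(x, "glucose_series")) return(x)
  glucose_series(x, interval_min = interval_min)
}

# internal: accept a series or bare numeric, return the value vector
series_values <- function(x) {
  if (inherits(x, "glucose_series")) x$values else as.numeric(x)
}

series_interval <- function(x, default = 5) {
  if (inherits(x, "glucose_series")) x$interval_min else default
}
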