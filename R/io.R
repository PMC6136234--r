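#' Convert glucose concentrations between mg/dl and mmol/l
#'
#' Uses the molar mass of glucose, 18.016 g/mol, so
#' `mmol = mgdl / 18.016` and the conversion is an exact bijection.
#'
#' @param x Numeric vector of concentrations.
#' @return Converted numeric vector.
#' @export
mgdl_to_mmol <- function(x) x / 18.016

#' @rdname mgdl_to_mmol
#' @export
mmol_to_mgdl <- function(x) x * 18.016

#' Write a glucose series to CSV
#'
#' The dialect is plain comma-separated text with a header row
#' `subject_id,timestamp,glucose_mmol_l`, '.' decimal separator, glucose
#' printed with 4 decimal places, and series-level metadata serialized as
#' `# key: value` comment lines before the header.
#'
#' @param series A [glucose_series()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cgm_csv <- function(series, path) {
  stopifnot(inherits(series, "glucose_series"))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing", call. = FALSE))
  on.exit(close(con))
  hdr <- c(
    sprintf("# interval_min: %g", series$interval_min),
    if (!is.na(series$group)) sprintf("# group: %s", series$group)
  )
  for (k in names(series$meta)) {
    v <- series$meta[[k]]
    hdr <- c(hdr, sprintf("# %s: %s", k, paste(format(v), collapse = " ")))
  }
  writeLines(hdr, con)
  t0 <- as.POSIXct(series$t0, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  ts <- format(t0 + (seq_along(series$values) - 1) * series$interval_min * 60,
               "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  writeLines("subject_id,timestamp,glucose_mmol_l", con)
  writeLines(sprintf("%s,%s,%.4f", series$subject_id, ts, series$values), con)
  invisible(path)
}

#' Read a glucose series from CSV
#'
#' Reads the dialect written by [write_cgm_csv()]: a header row naming at
#' least a glucose column (`glucose_mmol_l`, `glucose_mg_dl`, or `glucose`
#' with explicit `units`), optional `timestamp` (ISO-8601) and `subject_id`
#' columns, and `# key: value` comment lines carrying metadata. mg/dl
#' values are converted to mmol/l by division by 18.016. When timestamps
#' are present they must be strictly increasing and on a uniform grid;
#' missing grid rows become gaps which are linearly interpolated by
#' [fill_gaps()] subject to `max_gap_min`.
#'
#' @param path Input file path.
#' @param units `"auto"` (infer from the glucose column name), `"mmol"` or
#'   `"mgdl"`.
#' @param max_gap_min Longest gap (minutes between observed neighbours)
#'   that may be filled by interpolation; longer gaps raise a QC error.
#' @param interval_min Sampling interval assumed when no timestamp column
#'   exists.
#' @return A [glucose_series()].
#' @export
read_cgm_csv <- function(path, units = c("auto", "mmol", "mgdl"),
                         max_gap_min = 30, interval_min = 5) {
  units <- match.arg(units)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) {
      val <- m[3]
      num <- suppressWarnings(as.numeric(val))
      meta[[trimws(m[2])]] <- if (!is.na(num)) num else val
    }
  }
  df <- read.csv(text = lines[!grepl("^#", lines)],
                 stringsAsFactors = FALSE)
  glu_col <- intersect(c("glucose_mmol_l", "glucose_mg_dl", "glucose"),
                       names(df))
  if (!length(glu_col)) {
    stop("no glucose column found (expected glucose_mmol_l, glucose_mg_dl ",
         "or glucose)", call. = FALSE)
  }
  glu_col <- glu_col[[1]]
  if (units == "auto") {
    units <- switch(glu_col,
                    glucose_mmol_l = "mmol",
                    glucose_mg_dl = "mgdl",
                    stop("column '", glu_col, "' carries no units; pass ",
                         "units = 'mmol' or 'mgdl'", call. = FALSE))
  }
  values <- as.numeric(df[[glu_col]])
  if (units == "mgdl") values <- mgdl_to_mmol(values)

  subject_id <- if ("subject_id" %in% names(df)) {
    as.character(df$subject_id[[1]])
  } else "anon"
  group <- if (!is.null(meta$group)) as.character(meta$group) else NULL
  meta$group <- NULL

  t0 <- NULL
  if ("timestamp" %in% names(df)) {
    ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    if (anyNA(ts)) stop("unparseable timestamps", call. = FALSE)
    dmin <- as.numeric(diff(ts), units = "mins")
    if (any(dmin <= 0)) stop("timestamps are not monotone increasing",
                             call. = FALSE)
    step <- min(dmin)
    if (any(abs(dmin / step - round(dmin / step)) > 1e-6)) {
      stop("timestamps do not lie on a uniform grid", call. = FALSE)
    }
    interval_min <- step
    t0 <- ts[[1]]
    # expand to full grid; missed rows become NA gaps
    idx <- round(as.numeric(ts - ts[[1]], units = "mins") / step) + 1
    full <- rep(NA_real_, max(idx))
    full[idx] <- values
    values <- full
  } else {
    meta$assumed_grid <- TRUE
  }

  if (anyNA(values)) {
    filled <- fill_na_runs(values, interval_min, max_gap_min)
    values <- filled$values
    meta$interpolated_idx <- filled$idx
  }
  glucose_series(values, interval_min = interval_min,
                 subject_id = subject_id, t0 = t0, group = group,
                 meta = meta)
}

#' Fill short gaps in a glucose series by linear interpolation
#'
#' Gaps are runs of missing samples; a gap's duration is the time between
#' its observed neighbours. Gaps no longer than `max_gap_min` are filled
#' with [stats::approx()] (linear); any longer gap raises a QC error naming
#' its position. Interpolated sample indices are recorded in
#' `meta$interpolated_idx`.
#'
#' @param series A [glucose_series()] whose `meta$missing_idx` marks gap
#'   positions, or a numeric vector containing `NA` at gap positions (the
#'   vector form is wrapped after filling).
#' @param max_gap_min Longest fillable gap, minutes. Default 30 (6 samples
#'   at the 5-min rate).
#' @return A gap-free [glucose_series()].
#' @export
fill_gaps <- function(series, max_gap_min = 30) {
  if (inherits(series, "glucose_series")) {
    vals <- series$values
    miss <- series$meta$missing_idx
    if (!is.null(miss)) vals[miss] <- NA_real_
    if (!anyNA(vals)) return(series)
    filled <- fill_na_runs(vals, series$interval_min, max_gap_min)
    series$values <- filled$values
    series$meta$missing_idx <- NULL
    series$meta$interpolated_idx <- filled$idx
    return(series)
  }
  vals <- as.numeric(series)
  filled <- fill_na_runs(vals, 5, max_gap_min)
  out <- glucose_series(filled$values, interval_min = 5)
  out$meta$interpolated_idx <- filled$idx
  out
}

# interpolate NA runs; error on runs longer than max_gap_min
fill_na_runs <- function(values, interval_min, max_gap_min) {
  na_idx <- which(is.na(values))
  if (!length(na_idx)) return(list(values = values, idx = integer()))
  if (is.na(values[[1]]) || is.na(values[[length(values)]])) {
    stop("QC: series starts or ends with a gap; cannot interpolate",
         call. = FALSE)
  }
  runs <- split(na_idx, cumsum(c(1, diff(na_idx) != 1)))
  for (r in runs) {
    gap_min <- (length(r) + 1) * interval_min
    if (gap_min > max_gap_min) {
      stop(sprintf("QC: gap of %g min at samples %d-%d exceeds max_gap_min = %g",
                   gap_min, min(r), max(r), max_gap_min), call. = FALSE)
    }
  }
  obs <- which(!is.na(values))
  values[na_idx] <- approx(obs, values[obs], xout = na_idx)$y
  list(values = values, idx = na_idx)
}

#' Manufacturer-style validity screen for a CGM recording
#'
#' Applies the sensor-validity criterion used for ambulatory CGM data:
#' a recording passes when it has at least three paired sensor/meter
#' readings and their mean absolute relative difference is at most 28%.
#'
#' @param series A [glucose_series()] (carried through for labelling;
#'   the screen itself uses only the paired readings).
#' @param paired Data frame with numeric columns `sensor_value` and
#'   `meter_value` (mmol/l), optionally `time_offset_min`. May have zero
#'   rows.
#' @param max_mad_percent Pass threshold on the mean absolute difference,
#'   percent. Default 28.
#' @param min_pairs Minimum number of pairs. Default 3.
#' @return A list with `pass` (logical), `mad_percent`, `n_pairs` and
#'   `subject_id`.
#' @export
qc_validity <- function(series, paired, max_mad_percent = 28,
                        min_pairs = 3) {
  stopifnot(is.data.frame(paired))
  n_pairs <- nrow(paired)
  if (n_pairs > 0) {
    if (!all(c("sensor_value", "meter_value") %in% names(paired))) {
      stop("paired readings need sensor_value and meter_value columns",
           call. = FALSE)
    }
    if (any(paired$meter_value <= 0)) {
      stop("QC: meter_value must be positive", call. = FALSE)
    }
    mad_percent <- 100 * mean(abs(paired$sensor_value - paired$meter_value) /
                                paired$meter_value)
  } else {
    mad_percent <- NA_real_
  }
  list(pass = isTRUE(n_pairs >= min_pairs && mad_percent <= max_mad_percent),
       mad_percent = mad_percent, n_pairs = n_pairs,
       subject_id = if (inherits(series, "glucose_series"))
         series$subject_id else NA_character_)
}
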