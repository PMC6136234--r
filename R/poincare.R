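#' Lagged pairs for a Poincare plot
#'
#' Pairs each glucose value with the value one lag later:
#' `x = values[1..n-k]`, `y = values[k+1..n]` where `k` is the lag in
#' samples. All overlapping pairs (stride 1) are used.
#'
#' @param series A [glucose_series()] or numeric vector.
#' @param lag_min Time delay in minutes; must be a positive multiple of
#'   the sampling interval and shorter than the series.
#' @param interval_min Sampling interval when `series` is a bare vector.
#' @return A list with `x`, `y`, `lag_samples`, `n_pairs`.
#' @examples
#' lagged_pairs(c(1, 2, 3, 4), lag_min = 5)
#' @export
lagged_pairs <- function(series, lag_min = 60, interval_min = 5) {
  v <- series_values(series)
  dt <- series_interval(series, interval_min)
  k <- lag_min / dt
  if (lag_min <= 0 || abs(k - round(k)) > 1e-9) {
    stop("lag_min must be a positive multiple of the sampling interval (",
         dt, " min)", call. = FALSE)
  }
  k <- as.integer(round(k))
  n <- length(v)
  if (k >= n) stop("lag (", k, " samples) must be shorter than the series",
                   call. = FALSE)
  list(x = v[seq_len(n - k)], y = v[(k + 1):n],
       lag_samples = k, n_pairs = n - k)
}

#' Poincare plot descriptors SD1, SD2, SFE and AFE
#'
#' From the lagged pair cloud (G(t), G(t + lag)) the dispersion
#' perpendicular to the identity line is `sd1 = SD((x - y)/sqrt(2))` and
#' the dispersion along it is `sd2 = SD((x + y)/sqrt(2))` (sample, n-1
#' variance by default). The fitting-ellipse shape and area follow as
#' `SFE = SD2/SD1` and `AFE = pi * SD1 * SD2`.
#'
#' @inheritParams lagged_pairs
#' @param lag_min Time delay, minutes. Default 60, the delay found most
#'   informative for CGM plot geometry; 30 and 120 are common probes.
#' @param denominator `"n-1"` (sample variance, default) or `"n"`.
#' @return A list of class `poincare_result`: `lag_min`, `lag_samples`,
#'   `sd1`, `sd2`, `sfe`, `afe`, `n_pairs`. For a constant series
#'   `sd1 = sd2 = afe = 0` and `sfe` is `NA` with `sfe_undefined = TRUE`.
#' @examples
#' gs <- generate_cgm(cgm_profile_preset("T1D"), seed = 7)
#' poincare_descriptors(gs)
#' @export
poincare_descriptors <- function(series, lag_min = 60, interval_min = 5,
                                 denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  p <- lagged_pairs(series, lag_min, interval_min)
  d1 <- (p$x - p$y) / sqrt(2)
  d2 <- (p$x + p$y) / sqrt(2)
  v1 <- var(d1)
  v2 <- var(d2)
  if (denominator == "n") {
    f <- (p$n_pairs - 1) / p$n_pairs
    v1 <- v1 * f
    v2 <- v2 * f
  }
  sd1 <- sqrt(v1)
  sd2 <- sqrt(v2)
  structure(list(
    lag_min = lag_min, lag_samples = p$lag_samples,
    sd1 = sd1, sd2 = sd2,
    sfe = if (sd1 > 0) sd2 / sd1 else NA_real_,
    sfe_undefined = sd1 == 0,
    afe = pi * sd1 * sd2,
    n_pairs = p$n_pairs
  ), class = "poincare_result")
}

#' Ellipse shape and area from SD1 and SD2
#'
#' The closed-form descriptors of the Poincare fitting ellipse given its
#' axis dispersions: `SFE = SD2/SD1` (dimensionless) and
#' `AFE = pi * SD1 * SD2` (mmol^2/l^2).
#'
#' @param sd1,sd2 Axis dispersions, mmol/l, non-negative.
#' @return List with `sfe` and `afe`.
#' @examples
#' ellipse_metrics(1.48, 3.67)$afe  # about 17.06
#' @export
ellipse_metrics <- function(sd1, sd2) {
  stopifnot(sd1 >= 0, sd2 >= 0)
  list(sfe = if (sd1 > 0) sd2 / sd1 else NA_real_, afe = pi * sd1 * sd2)
}

#' @export
print.poincare_result <- function(x, ...) {
  cat(sprintf(
    "<poincare_result> lag %g min (%d samples), %d pairs\n  SD1 %.3f  SD2 %.3f  SFE %s  AFE %.3f mmol^2/l^2\n",
    x$lag_min, x$lag_samples, x$n_pairs, x$sd1, x$sd2,
    if (x$sfe_undefined) "undef" else sprintf("%.3f", x$sfe), x$afe))
  invisible(x)
}

#' Scatter plot of lagged glucose pairs
#'
#' Base-graphics Poincare plot with the identity line and the fitted
#' ellipse implied by SD1/SD2.
#'
#' @inheritParams poincare_descriptors
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the [poincare_descriptors()] result.
#' @export
plot_poincare <- function(series, lag_min = 60, ...) {
  p <- lagged_pairs(series, lag_min)
  d <- poincare_descriptors(series, lag_min)
  graphics::plot(p$x, p$y, pch = 16, cex = 0.4,
                 col = grDevices::adjustcolor("steelblue", 0.5),
                 xlab = "G(t) [mmol/l]",
                 ylab = sprintf("G(t + %g min) [mmol/l]", lag_min), ...)
  graphics::abline(0, 1, lty = 2)
  cx <- mean(p$x); cy <- mean(p$y)
  th <- seq(0, 2 * pi, length.out = 181)
  ex <- d$sd2 * cos(th) / sqrt(2) - d$sd1 * sin(th) / sqrt(2)
  ey <- d$sd2 * cos(th) / sqrt(2) + d$sd1 * sin(th) / sqrt(2)
  graphics::lines(cx + ex, cy + ey, col = "firebrick", lwd = 2)
  invisible(d)
}
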