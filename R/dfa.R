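#' Integrate a series about its mean
#'
#' The DFA profile: `y(k) = sum_{i=1..k} (B(i) - mean(B))`. By
#' construction `y(N) = 0` up to rounding.
#'
#' @param values Numeric vector (or [glucose_series()]), length >= 2.
#' @return Numeric vector `y` of the same length.
#' @examples
#' integrate_series(c(1, 2, 3))  # -1 -1 0
#' @export
integrate_series <- function(values) {
  v <- series_values(values)
  if (length(v) < 2) stop("need at least 2 values", call. = FALSE)
  cumsum(v - mean(v))
}

#' Detrended fluctuation at one box size
#'
#' Partitions the integrated profile `y` into `floor(N/n)` non-overlapping
#' boxes of `n` points anchored at the start (trailing remainder
#' discarded), fits an ordinary least-squares line in each box, and
#' returns the root-mean-square residual over all covered points:
#' `F(n) = sqrt( mean( (y - y_fit)^2 ) )`.
#'
#' @param y Integrated profile (from [integrate_series()]).
#' @param n Box size; at least `min_box` and at most `floor(N/2)`.
#' @param min_box Smallest admissible box. Default 4: 2-point boxes are
#'   fitted exactly by a line and 3-point boxes are near-degenerate, which
#'   would make `log F(n)` undefined or unstable.
#' @return `F(n)`, a non-negative scalar.
#' @export
fluctuation <- function(y, n, min_box = 4) {
  n <- as.integer(n)
  N <- length(y)
  if (n < min_box) stop("box size n = ", n, " below min_box = ", min_box,
                        call. = FALSE)
  if (n > N %/% 2) stop("box size n = ", n, " exceeds floor(N/2)",
                        call. = FALSE)
  nb <- N %/% n
  Y <- matrix(y[seq_len(nb * n)], nrow = n)
  t <- seq_len(n)
  tc <- t - mean(t)
  sxx <- sum(tc^2)
  slope <- colSums(Y * tc) / sxx
  resid <- Y - matrix(colMeans(Y), n, nb, byrow = TRUE) - outer(tc, slope)
  sqrt(sum(resid^2) / (nb * n))
}

#' Detrended fluctuation analysis with crossover-split exponents
#'
#' Computes the F(n) curve of a glucose series on an approximately
#' log-spaced integer grid of box sizes and fits two scaling exponents by
#' ordinary least squares of `log10 F(n)` on `log10 n`: the short-range
#' exponent `alpha1` over `short_range` and the long-range exponent
#' `alpha2` over `long_range`. The crossover box size (default n = 16,
#' i.e. about 1.25 h at 5-min sampling) belongs to both fit ranges.
#'
#' With first-order detrending the literal lower bound n = 2 yields
#' residual-free boxes (log F undefined), so the short range defaults to
#' n in \[4, 16\]; pass `min_box = 2` to include smaller boxes, in which
#' case zero-fluctuation grid points are dropped from the fits.
#'
#' @param series A [glucose_series()] or numeric vector.
#' @param short_range,long_range Integer 2-vectors `(n_min, n_max)` of box
#'   sizes for the two fits. Defaults `c(4, 16)` and `c(16, 144)`.
#' @param min_box Smallest admissible box size. Default 4.
#' @param points_per_decade Density of the log-spaced grid. Default 12.
#' @return A list of class `dfa_result`: `box_sizes`, `fluctuations`,
#'   `alpha1`, `alpha2`, `fit_range_short`, `fit_range_long`,
#'   `fit_r2_short`, `fit_r2_long`. An exponent is `NA` when fewer than 3
#'   usable grid points fall in its range.
#' @examples
#' x <- generate_fgn(0.7, 1024, seed = 1)
#' dfa_exponents(x)$alpha2
#' @export
dfa_exponents <- function(series, short_range = c(4, 16),
                          long_range = c(16, 144), min_box = 4,
                          points_per_decade = 12) {
  v <- series_values(series)
  N <- length(v)
  lo <- max(min_box, short_range[[1]])
  hi <- min(long_range[[2]], N %/% 2)
  if (N < 2 * long_range[[1]]) {
    stop("series too short for the long-range fit", call. = FALSE)
  }
  grid <- dfa_grid(lo, hi, points_per_decade)
  grid <- sort(unique(c(grid, min(max(16, lo), hi))))  # always keep crossover
  y <- integrate_series(v)
  Fn <- vapply(grid, function(n) fluctuation(y, n, min_box = min_box),
               numeric(1))
  usable <- Fn > 0
  fit_short <- fit_loglog(grid, Fn, c(lo, min(short_range[[2]], hi)), usable)
  fit_long <- fit_loglog(grid, Fn, c(max(long_range[[1]], lo), hi), usable)
  structure(list(
    box_sizes = grid, fluctuations = Fn,
    alpha1 = fit_short$slope, alpha2 = fit_long$slope,
    fit_range_short = c(lo, min(short_range[[2]], hi)),
    fit_range_long = c(max(long_range[[1]], lo), hi),
    fit_r2_short = fit_short$r2, fit_r2_long = fit_long$r2
  ), class = "dfa_result")
}

#' Single DFA scaling exponent over one box-size range
#'
#' Convenience wrapper fitting one log-log slope of F(n) versus n over
#' `fit_range`; the standard way to estimate the scaling exponent of a
#' long sequence (e.g. calibrating against fractional Gaussian noise,
#' whose exponent equals its Hurst parameter).
#'
#' @inheritParams dfa_exponents
#' @param fit_range Integer 2-vector of box sizes. Default `c(8, 256)`.
#' @return The fitted slope (scalar).
#' @export
dfa_alpha <- function(series, fit_range = c(8, 256), min_box = 4,
                      points_per_decade = 12) {
  v <- series_values(series)
  hi <- min(fit_range[[2]], length(v) %/% 2)
  lo <- max(fit_range[[1]], min_box)
  grid <- dfa_grid(lo, hi, points_per_decade)
  y <- integrate_series(v)
  Fn <- vapply(grid, function(n) fluctuation(y, n, min_box = min_box),
               numeric(1))
  fit_loglog(grid, Fn, c(lo, hi), Fn > 0)$slope
}

# ~log-spaced integer grid of box sizes
dfa_grid <- function(lo, hi, points_per_decade) {
  if (hi < lo) stop("no admissible box sizes (series too short)",
                    call. = FALSE)
  g <- unique(round(10^(seq(log10(lo), log10(hi),
                            by = 1 / points_per_decade))))
  sort(unique(c(g, lo, hi)))
}

# OLS of log10 F on log10 n restricted to [range], usable points only
fit_loglog <- function(grid, Fn, range, usable) {
  sel <- usable & grid >= range[[1]] & grid <= range[[2]]
  if (sum(sel) < 3) return(list(slope = NA_real_, r2 = NA_real_))
  lx <- log10(grid[sel])
  ly <- log10(Fn[sel])
  fit <- lm(ly ~ lx)
  list(slope = unname(coef(fit)[[2]]), r2 = summary(fit)$r.squared)
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf(
    "<dfa_result> %d box sizes n in [%d, %d]\n  alpha1 = %.3f (n %d-%d, R2 %.3f)   alpha2 = %.3f (n %d-%d, R2 %.3f)\n",
    length(x$box_sizes), min(x$box_sizes), max(x$box_sizes),
    x$alpha1, x$fit_range_short[1], x$fit_range_short[2], x$fit_r2_short,
    x$alpha2, x$fit_range_long[1], x$fit_range_long[2], x$fit_r2_long))
  invisible(x)
}

#' Log-log plot of the DFA fluctuation curve
#'
#' @param x A [dfa_exponents()] result.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot_dfa <- function(x, ...) {
  stopifnot(inherits(x, "dfa_result"))
  graphics::plot(log10(x$box_sizes), log10(x$fluctuations), pch = 16,
                 xlab = "log10 n (box size)", ylab = "log10 F(n)", ...)
  graphics::abline(v = log10(x$fit_range_short[2]), lty = 3)
  graphics::legend("topleft", bty = "n", legend = c(
    sprintf("alpha1 = %.2f", x$alpha1), sprintf("alpha2 = %.2f", x$alpha2)))
  invisible(x)
}
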