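#' Fractional Gaussian noise by circulant embedding
#'
#' Generates a zero-mean, unit-variance fractional Gaussian noise (fGn)
#' sequence with Hurst exponent `hurst` using the exact Davies–Harte
#' circulant-embedding construction: the target autocovariance
#' \eqn{\gamma(k) = (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})/2}
#' is embedded in a circulant matrix of order `2n` whose eigenvalues are
#' obtained by FFT; a complex Gaussian vector shaped by the eigenvalue
#' square roots is transformed back, yielding a draw with exactly the
#' requested covariance. For fGn the embedding is non-negative definite in
#' practice for all `hurst` in (0,1); should a (numerically) negative
#' eigenvalue appear it is clipped to zero and the result carries the
#' attribute `approximate = TRUE` (spectral approximation).
#'
#' fGn is the natural calibration substrate for detrended fluctuation
#' analysis: its DFA scaling exponent equals its Hurst exponent.
#'
#' @param hurst Hurst exponent, strictly between 0 and 1. `hurst = 0.5`
#'   gives white noise; larger values give persistent (long-memory) noise.
#' @param n Sequence length, at least 8.
#' @param seed Integer seed; the same `(hurst, n, seed)` always returns the
#'   identical sequence. The global RNG state is left untouched.
#' @return Numeric vector of length `n`, zero-mean unit-variance fGn (in
#'   distribution). Attribute `approximate` is set only when eigenvalue
#'   clipping occurred.
#' @examples
#' x <- generate_fgn(0.7, 512, seed = 1)
#' sd(x)  # close to 1
#' @export
generate_fgn <- function(hurst, n, seed) {
  if (!is.numeric(hurst) || length(hurst) != 1 ||
      hurst <= 0 || hurst >= 1) {
    stop("hurst must lie strictly inside (0, 1)", call. = FALSE)
  }
  n <- as.integer(n)
  if (is.na(n) || n < 8) stop("n must be at least 8", call. = FALSE)

  g <- fgn_autocov(0:n, hurst)              # gamma(0) .. gamma(n)
  row <- c(g[1:(n + 1)], rev(g[2:n]))       # circulant first row, length 2n
  lambda <- Re(fft(row))
  clipped <- FALSE
  tol <- -1e-10 * max(lambda)
  if (any(lambda < tol)) clipped <- TRUE
  lambda[lambda < 0] <- 0

  m <- 2L * n
  x <- withr::with_seed(seed, {
    z <- rnorm(m)
    a <- complex(length.out = m)
    a[1] <- sqrt(lambda[1]) * z[1]
    a[n + 1] <- sqrt(lambda[n + 1]) * z[2]
    k <- 2:n
    re <- z[2 * k - 1]
    im <- z[2 * k]
    a[k] <- sqrt(lambda[k] / 2) * complex(real = re, imaginary = im)
    a[m + 2 - k] <- Conj(a[k])
    Re(fft(a))[1:n] / sqrt(m)
  })
  if (clipped) attr(x, "approximate") <- TRUE
  x
}

# fGn autocovariance at integer lags k for Hurst exponent H (unit variance)
fgn_autocov <- function(k, H) {
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}
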