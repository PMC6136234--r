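#' Coarse-grain a time series
#'
#' Non-overlapping window averaging at scale `tau`: element `j` of the
#' output is the mean of values `(j-1)*tau + 1 .. j*tau`; the trailing
#' remainder is discarded, so the output has `floor(N / tau)` elements.
#'
#' @param values Numeric vector (or [glucose_series()]).
#' @param scale Integer scale factor `tau >= 1`, at most the series length.
#' @return Numeric vector of length `floor(N / tau)`.
#' @examples
#' coarse_grain(1:6, 2)  # 1.5 3.5 5.5
#' length(coarse_grain(rnorm(576), 5))  # 115
#' @export
coarse_grain <- function(values, scale) {
  v <- series_values(values)
  scale <- as.integer(scale)
  if (scale < 1) stop("scale must be >= 1", call. = FALSE)
  n <- length(v)
  if (scale > n) stop("scale exceeds series length", call. = FALSE)
  if (scale == 1) return(v)
  nb <- n %/% scale
  colMeans(matrix(v[seq_len(nb * scale)], nrow = scale))
}

#' Sample entropy
#'
#' SampEn(m, r) = -ln(A / B), where `B` counts ordered pairs (i != j) of
#' length-`m` templates within Chebyshev (max-abs) distance `r` of each
#' other, and `A` counts the same for length `m + 1`. Self-matches are
#' excluded. Templates are taken at every start index for which both the
#' m- and (m+1)-length template exist (i = 1..N-m), the convention of the
#' standard PhysioNet implementation, so that `A` and `B` are counted over
#' the same template set. Distances use `<= r`.
#'
#' @param values Numeric vector (or [glucose_series()]), length > m + 1.
#' @param m Template length, >= 1. Default 2.
#' @param r Absolute tolerance (same units as `values`), > 0.
#' @return Entropy in nats, with integer attributes `A` and `B` (the match
#'   counts). When `A = 0` (no long-template matches) the value is `NA`
#'   with attribute `undefined = TRUE`; it is never replaced by a
#'   surrogate constant.
#' @examples
#' sample_entropy(rep(5, 50), m = 2, r = 0.1)  # 0: every template matches
#' @export
sample_entropy <- function(values, m = 2, r) {
  v <- series_values(values)
  n <- length(v)
  m <- as.integer(m)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (n <= m + 1) stop("series too short for m = ", m, call. = FALSE)
  if (!is.numeric(r) || r <= 0) stop("r must be positive", call. = FALSE)

  nt <- n - m                       # template count (both lengths)
  # running Chebyshev distance between all template pairs, built up one
  # component at a time; O(n^2) memory but vectorized
  d <- matrix(0, nt, nt)
  for (k in 0:(m - 1)) {
    vi <- v[(1:nt) + k]
    d <- pmax(d, abs(outer(vi, vi, `-`)))
  }
  B <- sum(d <= r) - nt             # drop self-matches (diagonal)
  vi <- v[(1:nt) + m]
  d <- pmax(d, abs(outer(vi, vi, `-`)))
  A <- sum(d <= r) - nt

  if (B == 0 || A == 0) {
    return(structure(NA_real_, A = A, B = B, undefined = TRUE))
  }
  structure(-log(A / B), A = A, B = B)
}

#' Multiscale entropy and the complexity index
#'
#' Computes SampEn on coarse-grained versions of the series at scales
#' `1..max_scale` and sums them into the complexity index. The tolerance
#' `r = r_factor * SD` is computed once from the original (scale-1) series
#' and held fixed across scales, following the standard multiscale-entropy
#' tool convention.
#'
#' @param series A [glucose_series()] or numeric vector.
#' @param m Template length. Default 2.
#' @param r_factor Tolerance as a multiple of the series SD. Default 0.15.
#' @param max_scale Largest coarse-graining scale M. Default 5 (a 576-point
#'   48-h trace then retains 115 samples at the broadest scale).
#' @return A list of class `mse_result`: `params`, `r_value`,
#'   `sampen_by_scale` (named numeric, nats), `coarse_lengths`,
#'   `complexity_index` (sum over scales) and `partial` (`TRUE` when any
#'   scale's entropy was undefined; the index then sums the defined scales
#'   only and should be interpreted with care).
#' @examples
#' gs <- generate_cgm(cgm_profile_preset("ND"), seed = 3)
#' mse_index(gs)
#' @export
mse_index <- function(series, m = 2, r_factor = 0.15, max_scale = 5) {
  v <- series_values(series)
  m <- as.integer(m)
  max_scale <- as.integer(max_scale)
  stopifnot(m >= 1, r_factor > 0, max_scale >= 1)
  if (length(v) < max_scale * (m + 2)) {
    stop("series too short for max_scale = ", max_scale, call. = FALSE)
  }
  s0 <- sd(v)
  r <- r_factor * s0
  ent <- rep(NA_real_, max_scale)
  lens <- integer(max_scale)
  names(ent) <- names(lens) <- as.character(seq_len(max_scale))
  if (s0 == 0) {
    # constant series: every template matches itself-excluded set fully
    for (tau in seq_len(max_scale)) lens[tau] <- length(v) %/% tau
    ent[] <- 0
    return(structure(list(
      params = list(m = m, r_factor = r_factor, max_scale = max_scale),
      r_value = 0, sampen_by_scale = ent, coarse_lengths = lens,
      complexity_index = 0, partial = FALSE), class = "mse_result"))
  }
  for (tau in seq_len(max_scale)) {
    cg <- coarse_grain(v, tau)
    lens[tau] <- length(cg)
    ent[tau] <- sample_entropy(cg, m = m, r = r)
  }
  partial <- anyNA(ent)
  structure(list(
    params = list(m = m, r_factor = r_factor, max_scale = max_scale),
    r_value = r, sampen_by_scale = ent, coarse_lengths = lens,
    complexity_index = sum(ent, na.rm = TRUE), partial = partial
  ), class = "mse_result")
}

#' @export
print.mse_result <- function(x, ...) {
  cat(sprintf("<mse_result> m=%d, r=%.4f (%.2f x SD), scales 1..%d%s\n",
              x$params$m, x$r_value, x$params$r_factor,
              x$params$max_scale, if (x$partial) " [PARTIAL]" else ""))
  cat("  SampEn:", paste(sprintf("%.3f", x$sampen_by_scale),
                         collapse = " "), "\n")
  cat(sprintf("  complexity index: %.3f nats\n", x$complexity_index))
  invisible(x)
}
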