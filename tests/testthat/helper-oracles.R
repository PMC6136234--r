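# Independent reference implementations used as oracles in the tests.
# These are deliberately naive (double loops, per-box lm) and share no code
# with the package internals.

# Sample entropy by explicit double loop over ordered template pairs.
# Returns the integer match counts A (length m+1) and B (length m) and
# -ln(A/B); templates at i = 1..N-m, self-matches excluded, Chebyshev <= r.
sampen_bruteforce <- function(v, m, r) {
  n <- length(v)
  nt <- n - m
  A <- 0L
  B <- 0L
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (i == j) next
      dm <- max(abs(v[i:(i + m - 1)] - v[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1L
        if (max(dm, abs(v[i + m] - v[j + m])) <= r) A <- A + 1L
      }
    }
  }
  list(A = A, B = B,
       sampen = if (A > 0 && B > 0) -log(A / B) else NA_real_)
}

# Detrended fluctuation at one box size by per-box lm() fits.
fluctuation_reference <- function(y, n) {
  nb <- length(y) %/% n
  ss <- 0
  for (b in seq_len(nb)) {
    seg <- y[((b - 1) * n + 1):(b * n)]
    t <- seq_len(n)
    ss <- ss + sum(resid(lm(seg ~ t))^2)
  }
  sqrt(ss / (nb * n))
}

# small uniform test series wrapped as glucose_series
make_series <- function(values, interval_min = 5) {
  glucose_series(values, interval_min = interval_min)
}
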