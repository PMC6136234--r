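test_that("integration telescopes to zero", {
  expect_equal(integrate_series(c(1, 2, 3)), c(-1, -1, 0))
  expect_equal(integrate_series(rep(4, 10)), rep(0, 10))
  v <- generate_cgm(cgm_profile_preset("T1D"), n_points = 576, seed = 3)$values
  y <- integrate_series(v)
  expect_lt(abs(y[length(y)]), 1e-9 * length(v) * max(abs(v)))
})

test_that("F(n) is zero for profiles that are linear within every box", {
  y <- 0.5 * (1:128) - 3  # globally linear -> residual-free in any box
  for (n in c(4, 8, 16, 32)) expect_equal(fluctuation(y, n), 0)
  expect_error(fluctuation(y, 2), "min_box")
  expect_error(fluctuation(y, 100), "floor")
})

test_that("F(n) agrees with the naive per-box lm reference", {
  withr::with_seed(5, {
    for (rep in 1:15) {
      y <- integrate_series(rnorm(sample(100:400, 1)))
      n <- sample(4:40, 1)
      if (n > length(y) %/% 2) n <- length(y) %/% 2
      expect_equal(fluctuation(y, n), fluctuation_reference(y, n),
                   tolerance = 1e-10)
    }
  })
})

test_that("alpha is invariant to amplitude scaling; F scales linearly", {
  v <- generate_cgm(cgm_profile_preset("T2D"), n_points = 576, seed = 6)$values
  base <- dfa_exponents(v)
  k <- 3.7
  sc <- dfa_exponents(k * v)
  expect_equal(sc$alpha1, base$alpha1, tolerance = 1e-10)
  expect_equal(sc$alpha2, base$alpha2, tolerance = 1e-10)
  expect_equal(sc$fluctuations, k * base$fluctuations, tolerance = 1e-10)
  # adding a constant changes nothing (mean is removed before integration)
  off <- dfa_exponents(v + 10)
  expect_equal(off$fluctuations, base$fluctuations, tolerance = 1e-10)
})

test_that("576-point white-noise series give alpha1 and alpha2 near 0.5", {
  a <- vapply(1:60, function(s) {
    d <- dfa_exponents(generate_fgn(0.5, 576, s))
    c(d$alpha1, d$alpha2)
  }, numeric(2))
  expect_lt(abs(mean(a[1, ]) - 0.5), 0.15)
  expect_lt(abs(mean(a[2, ]) - 0.5), 0.15)
})

test_that("the crossover box size belongs to both fit ranges", {
  d <- dfa_exponents(generate_fgn(0.7, 576, 1))
  expect_true(16 %in% d$box_sizes)
  expect_equal(d$fit_range_short[2], 16)
  expect_equal(d$fit_range_long[1], 16)
  expect_true(all(d$box_sizes <= 288))
})

test_that("too-short ranges flag the exponent as undefined", {
  d <- dfa_exponents(generate_fgn(0.5, 64, 2), short_range = c(4, 16),
                     long_range = c(16, 144))
  # floor(64/2) = 32 leaves few long-range points but still >= 3
  expect_true(is.finite(d$alpha1))
  expect_error(dfa_exponents(generate_fgn(0.5, 20, 1)), "too short")
})
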