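test_that("coarse-graining averages non-overlapping windows", {
  expect_equal(coarse_grain(c(1, 2, 3, 4, 5, 6), 2), c(1.5, 3.5, 5.5))
  x <- rnorm(576)
  expect_identical(coarse_grain(x, 1), x)
  expect_length(coarse_grain(x, 5), 115)
  # remainder discarded
  expect_equal(coarse_grain(1:7, 3), c(2, 5))
  expect_error(coarse_grain(1:5, 6), "exceeds")
})

test_that("sample entropy matches the brute-force oracle (integer counts)", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      n <- sample(60:200, 1)
      v <- rnorm(n)
      r <- 0.15 * sd(v)
      fast <- sample_entropy(v, m = 2, r = r)
      slow <- sampen_bruteforce(v, 2, r)
      expect_identical(as.integer(attr(fast, "A")), slow$A)
      expect_identical(as.integer(attr(fast, "B")), slow$B)
      expect_equal(as.numeric(fast), slow$sampen)
    }
  })
})

test_that("sample entropy contracts: degenerate and undefined cases", {
  # constant series: every template pair matches -> A/B = 1 -> 0
  expect_equal(as.numeric(sample_entropy(rep(5, 60), 2, 0.1)), 0)
  # too short
  expect_error(sample_entropy(c(1, 2, 3), m = 2, r = 0.5), "too short")
  # widely separated values: no template matches at all -> undefined flag
  und <- sample_entropy(2^(1:30), m = 2, r = 1e-6)
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
})

test_that("SampEn is invariant to amplitude scaling when r scales with SD", {
  gs <- generate_cgm(cgm_profile_preset("T2D"), n_points = 576, seed = 9)
  base <- mse_index(gs)
  for (k in c(0.25, 4)) {
    scaled <- mse_index(gs$values * k)
    expect_equal(scaled$sampen_by_scale, base$sampen_by_scale,
                 tolerance = 1e-12)
  }
})

test_that("the complexity index sums the per-scale entropies", {
  gs <- generate_cgm(cgm_profile_preset("ND"), n_points = 576, seed = 2)
  ms <- mse_index(gs)
  expect_equal(ms$complexity_index, sum(ms$sampen_by_scale))
  expect_false(ms$partial)
  expect_equal(unname(ms$coarse_lengths),
               vapply(1:5, function(tau) 576L %/% tau, integer(1)))
  expect_equal(ms$r_value, 0.15 * sd(gs$values))
})

test_that("tolerance r is fixed from the scale-1 series", {
  # coarse-graining shrinks SD; recomputing r per scale would lower
  # entropies, so the fixed-r entropies must exceed per-scale-r ones
  gs <- generate_cgm(cgm_profile_preset("ND"), n_points = 576, seed = 8)
  ms <- mse_index(gs)
  cg5 <- coarse_grain(gs$values, 5)
  fixed_r <- as.numeric(sample_entropy(cg5, 2, ms$r_value))
  per_scale_r <- as.numeric(sample_entropy(cg5, 2, 0.15 * sd(cg5)))
  expect_equal(ms$sampen_by_scale[["5"]], fixed_r)
  expect_gt(per_scale_r, fixed_r)
})
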