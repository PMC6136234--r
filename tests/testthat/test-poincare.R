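test_that("lagged pairs are all overlapping pairs at the requested delay", {
  p <- lagged_pairs(c(1, 2, 3, 4), lag_min = 5)
  expect_equal(p$x, c(1, 2, 3))
  expect_equal(p$y, c(2, 3, 4))
  gs <- make_series(seq_len(576))
  p60 <- lagged_pairs(gs, lag_min = 60)
  expect_equal(p60$lag_samples, 12)
  expect_equal(p60$n_pairs, 564)
  expect_error(lagged_pairs(gs, lag_min = 7), "multiple")
  expect_error(lagged_pairs(c(1, 2, 3), lag_min = 15), "shorter")
})

test_that("sd1^2 + sd2^2 equals Var(x) + Var(y) exactly", {
  for (s in 1:10) {
    gs <- generate_cgm(cgm_profile_preset("T2D"), n_points = 288, seed = s)
    d <- poincare_descriptors(gs, lag_min = 30)
    p <- lagged_pairs(gs, lag_min = 30)
    expect_equal(d$sd1^2 + d$sd2^2, var(p$x) + var(p$y),
                 tolerance = 1e-10)
  }
})

test_that("descriptors are offset-invariant and scale-covariant", {
  v <- generate_cgm(cgm_profile_preset("T1D"), n_points = 576, seed = 4)$values
  base <- poincare_descriptors(v)
  off <- poincare_descriptors(v + 3)
  expect_equal(off$sd1, base$sd1)
  expect_equal(off$sd2, base$sd2)
  expect_equal(off$sfe, base$sfe)
  expect_equal(off$afe, base$afe)
  k <- 2.5
  sc <- poincare_descriptors(k * v)
  expect_equal(sc$sd1, k * base$sd1)
  expect_equal(sc$sd2, k * base$sd2)
  expect_equal(sc$sfe, base$sfe)
  expect_equal(sc$afe, k^2 * base$afe)
})

test_that("rotated-coordinate variances match the bivariate closed form", {
  # For pairs (x, y): sd1^2 -> (Var x + Var y)/2 - Cov, sd2^2 -> ... + Cov.
  # Simulate a large correlated pair cloud with known covariance.
  withr::with_seed(11, {
    n <- 1e5
    rho <- 0.7
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  })
  d1 <- sd((x - y) / sqrt(2))
  d2 <- sd((x + y) / sqrt(2))
  expect_equal(d1^2, (var(x) + var(y)) / 2 - cov(x, y), tolerance = 1e-10)
  expect_equal(d2^2, (var(x) + var(y)) / 2 + cov(x, y), tolerance = 1e-10)
  expect_lt(abs(d1^2 - (1 - rho)), 0.01 * (1 - rho) + 0.01)
  expect_lt(abs(d2^2 - (1 + rho)), 0.01 * (1 + rho) + 0.01)
})

test_that("SFE is near 1 for uncorrelated series and above 1 under lag correlation", {
  sfe_iid <- mean(vapply(1:20, function(s) {
    poincare_descriptors(5 + generate_fgn(0.5, 1000, s) * 0.2,
                         lag_min = 5)$sfe
  }, numeric(1)))
  expect_lt(abs(sfe_iid - 1), 0.05)
  # AR(1) with rho = 0.9 at lag 1: sfe ~ sqrt((1+rho)/(1-rho)) > 1
  sfe_ar <- vapply(1:10, function(s) {
    e <- withr::with_seed(s, rnorm(1500))
    x <- as.numeric(stats::filter(e, 0.9, method = "recursive"))[-(1:100)]
    poincare_descriptors(10 + 0.1 * x, lag_min = 5)$sfe
  }, numeric(1))
  expect_true(all(sfe_ar > 1.5))
})

test_that("a constant series degenerates gracefully", {
  d <- poincare_descriptors(rep(5, 100))
  expect_equal(d$sd1, 0)
  expect_equal(d$sd2, 0)
  expect_equal(d$afe, 0)
  expect_true(d$sfe_undefined)
  expect_true(is.na(d$sfe))
})

test_that("ellipse metrics follow SFE = SD2/SD1 and AFE = pi SD1 SD2", {
  em <- ellipse_metrics(2, 3)
  expect_equal(em$sfe, 1.5)
  expect_equal(em$afe, 6 * pi)
  expect_true(is.na(ellipse_metrics(0, 3)$sfe))
})
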