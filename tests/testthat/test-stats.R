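make_group_table <- function(means, n = 10, seed = 1, sd = 1) {
  withr::with_seed(seed, {
    do.call(rbind, lapply(names(means), function(g) {
      data.frame(group = g, y = rnorm(n, means[[g]], sd))
    }))
  })
}

test_that("clearly separated groups are detected, identical ones are not", {
  tab <- make_group_table(list(A = 0, B = 0, C = 10), n = 12, seed = 3)
  res <- compare_groups(tab, "y")
  expect_lt(res$anova$p, 1e-6)
  pw <- res$pairwise
  ab <- pw$p_holm[pw$group1 == "A" & pw$group2 == "B"]
  expect_gt(ab, 0.05)
  expect_lt(max(pw$p_holm[pw$group2 == "C" | pw$group1 == "C"]), 1e-6)
})

test_that("Holm adjustment dominates raw p and matches the step-down rule", {
  tab <- make_group_table(list(A = 0, B = 0.5, C = 1), n = 15, seed = 7)
  pw <- compare_groups(tab, "y")$pairwise
  expect_true(all(pw$p_holm >= pw$p_raw))
  expect_equal(pw$p_holm, p.adjust(pw$p_raw, "holm"))
  # hand-checked step-down example: raw (.01, .04, .03) -> (.03, .06, .06)
  expect_equal(p.adjust(c(0.01, 0.04, 0.03), "holm"), c(0.03, 0.06, 0.06))
})

test_that("standardized beta of a single-term model is the Pearson r", {
  withr::with_seed(2, {
    tab <- data.frame(x = rnorm(80))
    tab$y <- 0.6 * tab$x + rnorm(80)
  })
  rep1 <- standardized_regression(tab, "y", "x")
  expect_equal(rep1$coefficients$beta, cor(tab$x, tab$y),
               tolerance = 1e-10)
  expect_equal(rep1$coefficients$vif, 1)
  # exact dependence
  tab$z <- tab$x
  rep2 <- suppressWarnings(standardized_regression(tab, "z", "x"))
  expect_equal(rep2$coefficients$beta, 1, tolerance = 1e-12)
  expect_equal(rep2$r2_adj, 1, tolerance = 1e-12)
})

test_that("null regressions show vanishing betas and adj R2", {
  withr::with_seed(4, {
    tab <- data.frame(y = rnorm(500), a = rnorm(500), b = rnorm(500),
                      c = rnorm(500))
  })
  rep <- standardized_regression(tab, "y", c("a", "b", "c"))
  expect_true(all(abs(rep$coefficients$beta) < 0.15))
  expect_lt(abs(rep$r2_adj), 0.02)
  expect_true(all(rep$coefficients$vif >= 1 & rep$coefficients$vif < 1.1))
  expect_gt(rep$durbin_watson, 1.7)
  expect_lt(rep$durbin_watson, 2.3)
})

test_that("degenerate designs are refused with a named error", {
  withr::with_seed(5, tab <- data.frame(y = rnorm(30), a = rnorm(30)))
  tab$b <- tab$a
  expect_error(standardized_regression(tab, "y", c("a", "b")), "collinear")
  tab$const <- 1
  expect_error(standardized_regression(tab, "y", c("a", "const")),
               "constant")
})

test_that("spearman matrix has unit diagonal and exact +/-1 extremes", {
  withr::with_seed(6, {
    tab <- data.frame(u = rnorm(40))
    tab$up <- tab$u^3           # monotone transform: rho = 1
    tab$down <- -tab$u          # rho = -1
  })
  sm <- spearman_matrix(tab, c("u", "up", "down"))
  expect_equal(unname(diag(sm$rho)), rep(1, 3))
  expect_equal(sm$rho["u", "up"], 1)
  expect_equal(sm$rho["u", "down"], -1)
  expect_true(isSymmetric(sm$rho))
})

test_that("TIR models recover a constructed dominant predictor", {
  co <- generate_cohort(cohort_spec(list(T2D = 60), n_points = 288,
                                    seed = 21))
  tab <- compute_cohort_table(co$series, co$subjects)
  # TIR built as a decreasing function of SD2 plus noise
  tab$tir_hours_per_day <- withr::with_seed(
    22, 20 - 3 * scale(tab$sd2)[, 1] + rnorm(nrow(tab), sd = 0.5))
  rep <- tir_models(tab, "sd2")
  co_sd2 <- rep$coefficients[rep$coefficients$term == "sd2", ]
  co_cv <- rep$coefficients[rep$coefficients$term == "cv_percent", ]
  expect_lt(co_sd2$beta, 0)
  expect_gt(abs(co_sd2$beta), abs(co_cv$beta))
  expect_lt(co_sd2$p, 0.001)
  expect_error(tir_models(tab, "cv_percent"), "collinearity")
})

test_that("all-noise TIR yields no spurious dominant predictor", {
  co <- generate_cohort(cohort_spec(list(T2D = 50), n_points = 96,
                                    seed = 31))
  tab <- compute_cohort_table(co$series, co$subjects)
  hits <- vapply(1:60, function(s) {
    tab$tir_hours_per_day <- withr::with_seed(1000 + s,
                                              rnorm(nrow(tab), 15, 3))
    rep <- tir_models(tab, "sd2", stepwise = FALSE)
    sum(rep$coefficients$p < 0.05)
  }, numeric(1))
  # 8 terms at nominal 5%: expect ~0.4 significant terms per run
  expect_lt(mean(hits) / 8, 0.12)
})

test_that("paired comparison handles identical and shifted tables", {
  tab <- data.frame(subject_id = paste0("s", 1:8), afe = (1:8) * 1.5)
  same <- paired_before_after(tab, tab, "afe")
  expect_equal(same$mean_difference, 0)
  expect_true(same$zero_variance)
  expect_equal(same$p, 1)
  shifted <- tab
  shifted$afe <- tab$afe - 1
  res <- paired_before_after(tab, shifted, "afe")
  expect_equal(res$mean_difference, -1)
  expect_true(res$zero_variance)
  # genuine paired data
  noisy <- tab
  noisy$afe <- withr::with_seed(9, tab$afe - 2 + rnorm(8, sd = 0.3))
  res2 <- paired_before_after(tab, noisy, "afe")
  expect_false(res2$zero_variance)
  expect_lt(res2$p, 0.001)
  expect_error(paired_before_after(tab, tab[-1, ], "afe"), "same subjects")
})
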