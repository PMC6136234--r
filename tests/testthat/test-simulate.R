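test_that("generated series are bitwise reproducible from the seed", {
  p <- cgm_profile_preset("T2D")
  expect_identical(generate_cgm(p, seed = 123), generate_cgm(p, seed = 123))
  spec <- cohort_spec(list(ND = 2, T1D = 2), n_points = 96, seed = 77)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
})

test_that("realized mean and %CV hit the profile targets for all presets", {
  for (label in c("ND", "T2D", "T1D")) {
    p <- cgm_profile_preset(label)
    stats <- vapply(1:100, function(s) {
      gv <- compute_gv(generate_cgm(p, n_points = 576, seed = s))
      c(gv$mean_glucose, gv$cv_percent)
    }, numeric(2))
    expect_true(all(abs(stats[1, ] / p$mean_glucose - 1) < 0.01),
                label = paste(label, "mean within 1%"))
    expect_true(all(abs(stats[2, ] / p$cv_percent - 1) < 0.10),
                label = paste(label, "%CV within 10% relative"))
  }
})

test_that("a degenerate profile yields a constant series at its mean", {
  p <- sim_profile(mean_glucose = 6.5, cv_percent = 0, circadian_amp = 0,
                   meal_amp = 0, noise_sd = 0, fgn_sd = 0)
  gs <- generate_cgm(p, n_points = 64, seed = 1)
  expect_equal(gs$values, rep(6.5, 64))
})

test_that("T1D realized %CV always exceeds ND realized %CV", {
  cv <- function(p, s) compute_gv(generate_cgm(p, seed = s))$cv_percent
  nd <- vapply(1:100, function(s) cv(cgm_profile_preset("ND"), s),
               numeric(1))
  t1d <- vapply(1:100, function(s) cv(cgm_profile_preset("T1D"), s),
                numeric(1))
  expect_gt(min(t1d), max(nd))
})

test_that("heavy clipping is flagged, not fatal", {
  p <- sim_profile(mean_glucose = 3.2, cv_percent = 60)
  gs <- generate_cgm(p, n_points = 576, seed = 1)
  expect_gt(gs$meta$clip_fraction, 0.05)
  expect_true(gs$meta$cv_warning)
  expect_true(all(gs$values >= 2.2))
})

test_that("cohorts have one series per subject with unique ids", {
  spec <- cohort_spec(list(ND = 12, T2D = 143, T1D = 22), n_points = 32,
                      seed = 5)
  co <- generate_cohort(spec)
  expect_length(co$series, 177)
  expect_equal(nrow(co$subjects), 177)
  ids <- vapply(co$series, function(s) s$subject_id, character(1))
  expect_false(anyDuplicated(ids) > 0)
  expect_setequal(ids, co$subjects$subject_id)
  expect_true(all(vapply(co$series, length, integer(1)) == 32))
  # covariate sanity: therapy coding per group
  expect_true(all(co$subjects$therapy_code[co$subjects$group == "ND"] == 1))
  expect_true(all(co$subjects$therapy_code[co$subjects$group == "T1D"] == 4))
  expect_true(all(co$subjects$therapy_code %in% 1:4))
  expect_true(all(co$subjects$diabetes_duration[co$subjects$group == "ND"] == 0))
})

test_that("cohort specs validate and load from YAML", {
  expect_error(cohort_spec(list()), "at least one group")
  expect_error(cohort_spec(list(ND = 0)), "at least one subject")
  expect_error(cohort_spec(list(ND = 2), n_points = 8), "n_points")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("groups:", "  ND: 2", "  T1D: 3",
               "n_points: 96", "seed: 9"), path)
  spec <- read_cohort_spec(path)
  expect_s3_class(spec, "cohort_spec")
  expect_equal(spec$n_points, 96)
  expect_equal(vapply(spec$groups, function(g) g$n, 1L), c(2L, 3L))
})
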