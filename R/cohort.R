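#' Per-subject metric table for a cohort
#'
#' Runs every analysis stage on each series and joins the results to the
#' covariate table: conventional metrics (mean, SD, %CV, TIR), Poincare
#' descriptors (SD1, SD2, SFE, AFE), multiscale entropy (scale-1 SampEn
#' and the complexity index) and DFA exponents (alpha1, alpha2). This
#' table is the input to all cohort-level statistics.
#'
#' @param series List of [glucose_series()] (or a single series).
#' @param subjects Optional covariate tibble with a `subject_id` column
#'   (as produced by [generate_cohort()]); joined by subject id.
#' @param lag_min Poincare lag, minutes.
#' @param tir_range Target range for TIR, mmol/l.
#' @param mse_params List with `m`, `r_factor`, `max_scale`.
#' @param dfa_short,dfa_long,dfa_min_box DFA fit ranges and smallest box.
#' @return A tibble, one row per subject: identifying columns, covariates
#'   when supplied, and 13 metric columns (`n_points`, `mean_glucose`,
#'   `sd`, `cv_percent`, `tir_hours_per_day`, `sd1`, `sd2`, `sfe`, `afe`,
#'   `sampen_scale1`, `complexity_index`, `alpha1`, `alpha2`).
#' @examples
#' co <- generate_cohort(cohort_spec(list(ND = 2, T1D = 2), n_points = 288))
#' compute_cohort_table(co$series, co$subjects)
#' @export
compute_cohort_table <- function(series, subjects = NULL, lag_min = 60,
                                 tir_range = c(3.9, 8.9),
                                 mse_params = list(m = 2, r_factor = 0.15,
                                                   max_scale = 5),
                                 dfa_short = c(4, 16), dfa_long = c(16, 144),
                                 dfa_min_box = 4) {
  if (inherits(series, "glucose_series")) series <- list(series)
  rows <- lapply(series, function(gs) {
    gv <- compute_gv(gs, tir_range[[1]], tir_range[[2]])
    pc <- poincare_descriptors(gs, lag_min = lag_min)
    ms <- mse_index(gs, m = mse_params$m, r_factor = mse_params$r_factor,
                    max_scale = mse_params$max_scale)
    df <- dfa_exponents(gs, short_range = dfa_short, long_range = dfa_long,
                        min_box = dfa_min_box)
    tibble::tibble(
      subject_id = gs$subject_id, group = gs$group,
      n_points = length(gs$values),
      mean_glucose = gv$mean_glucose, sd = gv$sd,
      cv_percent = gv$cv_percent,
      tir_hours_per_day = gv$tir_hours_per_day,
      sd1 = pc$sd1, sd2 = pc$sd2, sfe = pc$sfe, afe = pc$afe,
      sampen_scale1 = ms$sampen_by_scale[["1"]],
      complexity_index = ms$complexity_index,
      alpha1 = df$alpha1, alpha2 = df$alpha2
    )
  })
  tab <- do.call(rbind, rows)
  if (anyDuplicated(tab$subject_id)) {
    stop("duplicate subject ids in cohort", call. = FALSE)
  }
  if (!is.null(subjects)) {
    stopifnot("subject_id" %in% names(subjects))
    cov <- subjects[, setdiff(names(subjects), "group"), drop = FALSE]
    tab <- merge(tab, cov, by = "subject_id", sort = FALSE)
    tab <- tibble::as_tibble(tab)
  }
  tab
}
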