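#' Group comparison: one-way ANOVA plus Holm-corrected pairwise t tests
#'
#' One-way analysis of variance across the groups, followed by all
#' pairwise two-sided Student t tests with Holm step-down adjustment over
#' the pairwise family.
#'
#' @param table Data frame with a grouping column and the metric column.
#' @param metric Name of the numeric column to compare.
#' @param group Name of the grouping column. Default `"group"`.
#' @param var_equal Use pooled-variance Student t tests (default `TRUE`);
#'   set `FALSE` for Welch.
#' @return A list with `anova` (tibble: `f`, `p`, `df1`, `df2`) and
#'   `pairwise` (tibble: `group1`, `group2`, `t`, `p_raw`, `p_holm`).
#' @examples
#' co <- generate_cohort(cohort_spec(list(ND = 5, T1D = 5), n_points = 288))
#' tab <- compute_cohort_table(co$series)
#' compare_groups(tab, "cv_percent")$anova
#' @export
compare_groups <- function(table, metric, group = "group",
                           var_equal = TRUE) {
  g <- factor(table[[group]])
  y <- table[[metric]]
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(tapply(y, g, length) < 2)) {
    stop("every group needs at least 2 subjects", call. = FALSE)
  }
  av <- anova(aov(y ~ g))
  levs <- levels(g)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  pw <- lapply(pairs, function(p) {
    tt <- t.test(y[g == p[[1]]], y[g == p[[2]]], var.equal = var_equal)
    data.frame(group1 = p[[1]], group2 = p[[2]],
               t = unname(tt$statistic), p_raw = tt$p.value,
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, pw)
  pw$p_holm <- p.adjust(pw$p_raw, method = "holm")
  list(anova = tibble::tibble(f = av$`F value`[[1]], p = av$`Pr(>F)`[[1]],
                              df1 = av$Df[[1]], df2 = av$Df[[2]]),
       pairwise = tibble::as_tibble(pw))
}

#' Spearman correlation matrix with p-values
#'
#' Rank-based correlations (ties mid-ranked) between every pair of the
#' requested columns, with two-sided p-values from [stats::cor.test()]
#' (asymptotic under ties).
#'
#' @param table Data frame.
#' @param columns Character vector of numeric column names (>= 2).
#' @return A list with matrices `rho` (diagonal 1) and `p` (diagonal `NA`).
#' @export
spearman_matrix <- function(table, columns) {
  stopifnot(length(columns) >= 2, all(columns %in% names(table)))
  d <- table[, columns, drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 complete rows", call. = FALSE)
  k <- length(columns)
  rho <- diag(1, k)
  p <- matrix(NA_real_, k, k)
  dimnames(rho) <- dimnames(p) <- list(columns, columns)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ct <- suppressWarnings(
        cor.test(d[[i]], d[[j]], method = "spearman", exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(rho = rho, p = p)
}

#' Standardized multiple linear regression with diagnostics
#'
#' Ordinary least squares on the z-scored response and z-scored continuous
#' terms: coefficients are standardized betas. `sex` is coded 0/1 (M = 0,
#' F = 1) and `therapy_code` enters as a single ordinal numeric 1-4. The
#' report includes two-sided p-values, adjusted R-squared, the variance
#' inflation factor per term (via [car::vif()]) and the Durbin-Watson
#' statistic on residuals in table row order (via [lmtest::dwtest()]).
#'
#' @param table Data frame.
#' @param response Name of the response column.
#' @param terms Character vector of predictor column names.
#' @return A list of class `regression_report`: `response`, `coefficients`
#'   (tibble: `term`, `beta`, `p`, `vif`), `r2_adj`, `durbin_watson`, `n`.
#' @examples
#' co <- generate_cohort(cohort_spec(list(T2D = 40), n_points = 288))
#' tab <- compute_cohort_table(co$series, co$subjects)
#' standardized_regression(tab, "tir_hours_per_day", c("cv_percent", "sd2"))
#' @export
standardized_regression <- function(table, response, terms) {
  stopifnot(response %in% names(table), all(terms %in% names(table)))
  d <- encode_model_frame(table, c(response, terms))
  d <- d[complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n <= length(terms) + 2) stop("too few rows for the model",
                                   call. = FALSE)
  const <- vapply(d, function(x) sd(x) == 0, logical(1))
  if (any(const[terms])) {
    stop("constant term(s): ", paste(terms[const[terms]], collapse = ", "),
         call. = FALSE)
  }
  z <- as.data.frame(lapply(d, function(x) (x - mean(x)) / sd(x)))
  fit <- lm(stats::reformulate(terms, response), data = z)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("perfectly collinear term(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sm <- summary(fit)
  vif <- if (length(terms) >= 2) car::vif(fit)[terms] else
    setNames(rep(1, length(terms)), terms)
  dw <- unname(lmtest::dwtest(fit)$statistic)
  structure(list(
    response = response,
    coefficients = tibble::tibble(
      term = terms,
      beta = unname(coef(fit)[terms]),
      p = sm$coefficients[terms, "Pr(>|t|)"],
      vif = unname(vif)),
    r2_adj = sm$adj.r.squared,
    durbin_watson = dw, n = n
  ), class = "regression_report")
}

# numeric-encode sex and therapy_code; leave other columns as numeric
encode_model_frame <- function(table, cols) {
  d <- table[, cols, drop = FALSE]
  if ("sex" %in% cols) d$sex <- as.numeric(d$sex %in% c("F", "f", 1))
  if ("therapy_code" %in% cols) d$therapy_code <- as.numeric(d$therapy_code)
  as.data.frame(lapply(d, as.numeric))
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("<regression_report> %s ~ %d terms (n = %d)\n", x$response,
              nrow(x$coefficients), x$n))
  print(as.data.frame(x$coefficients), digits = 3)
  cat(sprintf("  adj R2 = %.3f, Durbin-Watson = %.2f\n",
              x$r2_adj, x$durbin_watson))
  invisible(x)
}

#' TIR regression on the core covariate model plus a dynamical index
#'
#' Fits `TIR ~ age + sex + diabetes_duration + bmi + carb_intake +
#' therapy_code + %CV + index` as a standardized regression. Because
#' diabetes duration is undefined for non-diabetic subjects, the default
#' fits patients only (`subjects = "patients"` drops ND rows); with
#' `subjects = "all"`, duration is removed from the covariates instead.
#' Optional forward stepwise selection of the core covariates retains only
#' those entering at `p_enter` (the index and %CV are always kept).
#'
#' @param table Cohort table from [compute_cohort_table()] joined to
#'   covariates.
#' @param index_column Name of the dynamical-index column (e.g. `"sd2"`).
#' @param tir_column,cv_column Response and conventional-GV column names.
#' @param covariates Core covariates.
#' @param subjects `"patients"` (drop the ND group; default) or `"all"`.
#' @param stepwise Forward-select covariates at `p_enter`? Default `FALSE`
#'   (all covariates enter).
#' @param p_enter Inclusion threshold for stepwise selection.
#' @return A `regression_report` (see [standardized_regression()]).
#' @export
tir_models <- function(table, index_column,
                       tir_column = "tir_hours_per_day",
                       cv_column = "cv_percent",
                       covariates = c("age", "sex", "diabetes_duration",
                                      "bmi", "carb_intake", "therapy_code"),
                       subjects = c("patients", "all"),
                       stepwise = FALSE, p_enter = 0.05) {
  subjects <- match.arg(subjects)
  if (subjects == "patients" && "group" %in% names(table)) {
    table <- table[table$group != "ND", , drop = FALSE]
  } else {
    covariates <- setdiff(covariates, "diabetes_duration")
  }
  covariates <- intersect(covariates, names(table))
  base_terms <- c(cv_column, index_column)
  if (identical(index_column, cv_column)) {
    stop("index column identical to the conventional GV column ",
         "(perfect collinearity)", call. = FALSE)
  }
  terms <- if (stepwise) {
    c(base_terms, forward_select(table, tir_column, base_terms,
                                 covariates, p_enter))
  } else {
    c(covariates, base_terms)
  }
  standardized_regression(table, tir_column, terms)
}

# forward selection of candidates on top of fixed base terms
forward_select <- function(table, response, base, candidates, p_enter) {
  chosen <- character()
  repeat {
    remaining <- setdiff(candidates, chosen)
    if (!length(remaining)) break
    ps <- vapply(remaining, function(cand) {
      fit <- standardized_regression(table, response,
                                     c(base, chosen, cand))
      fit$coefficients$p[fit$coefficients$term == cand]
    }, numeric(1))
    if (min(ps) >= p_enter) break
    chosen <- c(chosen, remaining[[which.min(ps)]])
  }
  chosen
}

#' Paired before/after comparison
#'
#' Two-sided paired Student t test of one metric between two cohort tables
#' sharing the same subjects (e.g. before and after a therapy switch).
#'
#' @param before,after Data frames with `subject_id` and the metric
#'   column; the same subject set in both.
#' @param metric Name of the metric column.
#' @return A list: `mean_difference` (`mean(after - before)`), `t`, `p`,
#'   `n`, and `zero_variance` (`TRUE` when all differences are identical,
#'   in which case `t` and `p` are `NA`).
#' @export
paired_before_after <- function(before, after, metric) {
  stopifnot("subject_id" %in% names(before), "subject_id" %in% names(after),
            metric %in% names(before), metric %in% names(after))
  if (!setequal(before$subject_id, after$subject_id)) {
    stop("before/after tables must contain the same subjects",
         call. = FALSE)
  }
  a <- after[match(before$subject_id, after$subject_id), , drop = FALSE]
  diff <- a[[metric]] - before[[metric]]
  md <- mean(diff)
  if (length(diff) < 2 || sd(diff) == 0) {
    return(list(mean_difference = md, t = NA_real_,
                p = if (all(diff == 0)) 1 else NA_real_,
                n = length(diff), zero_variance = TRUE))
  }
  tt <- t.test(a[[metric]], before[[metric]], paired = TRUE)
  list(mean_difference = md, t = unname(tt$statistic), p = tt$p.value,
       n = length(diff), zero_variance = FALSE)
}
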