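# Cohort statistical layer: normality check, one-way ANOVA with
# pooled-variance group confidence intervals, two-factor interaction
# model, and the multivariate OLS models (full age range and age 50-73).

.check_cohort <- function(cohort, cols = c("fd")) {
  rf_assert(inherits(cohort, "data.frame"), "rf_input_error",
            "cohort must be a data.frame")
  for (cl in cols) {
    rf_assert(cl %in% names(cohort), "rf_input_error",
              "cohort lacks column '%s'", cl)
    rf_assert(!anyNA(cohort[[cl]]), "rf_input_error",
              "missing values in column '%s'", cl)
  }
  invisible(cohort)
}

#' Anderson-Darling test of normality
#'
#' Tests whether values are consistent with a normal distribution with
#' mean and variance estimated from the data (the case-both-parameters-
#' estimated statistic with the standard `(1 + 0.75/n + 2.25/n^2)`
#' small-sample correction, as implemented in the nortest package).
#'
#' @param values numeric vector, at least 8 observations.
#' @return A list with `statistic` and `p_value`.
#' @export
anderson_darling_normality <- function(values) {
  rf_assert(is.numeric(values) && length(values) >= 8, "rf_stats_error",
            "Anderson-Darling test needs at least 8 observations")
  rf_assert(stats::sd(values) > 0, "rf_stats_error",
            "constant input: zero variance")
  t <- nortest::ad.test(values)
  list(statistic = unname(t$statistic), p_value = unname(t$p.value))
}

#' Mean with t confidence interval
#'
#' @param values numeric vector, at least 2 observations.
#' @param alpha two-sided error level (0.05 for a 95% interval).
#' @return A list with `mean`, `ci_low`, `ci_high`.
#' @export
mean_ci <- function(values, alpha = 0.05) {
  rf_assert(is.numeric(values) && length(values) >= 2, "rf_stats_error",
            "need at least 2 values")
  n <- length(values)
  m <- mean(values)
  half <- stats::qt(1 - alpha / 2, n - 1) * stats::sd(values) / sqrt(n)
  list(mean = m, ci_low = m - half, ci_high = m + half)
}

#' One-way ANOVA on fractal dimension
#'
#' F-test of equal mean FD across the levels of a grouping column, with
#' per-level means and 95% confidence intervals computed from the pooled
#' residual variance (the convention that makes interval widths
#' reproducible from the group sizes and a single variance estimate).
#' When there is no between-group variance the test reports `F = 0`,
#' `p = 1`.
#'
#' @param cohort a `cohort_table` (or data.frame with an `fd` column).
#' @param factor_col name of the grouping column.
#' @param alpha error level for the per-level intervals.
#' @return A list with `summaries` (data.frame: level, n, mean_fd, ci_low,
#'   ci_high), `f_statistic`, `df`, and `p_value`.
#' @export
group_anova <- function(cohort, factor_col = "diabetes", alpha = 0.05) {
  .check_cohort(cohort, c("fd", factor_col))
  f <- factor(cohort[[factor_col]])
  rf_assert(nlevels(f) >= 2, "rf_stats_error",
            "factor '%s' must have at least 2 levels", factor_col)
  ns <- table(f)
  if (any(ns < 2))
    rf_stop("rf_stats_error", "every level needs n >= 2 (got %s)",
            paste(ns, collapse = ","))
  y <- cohort$fd
  N <- length(y); k <- nlevels(f)
  means <- tapply(y, f, mean)
  ssb <- sum(ns * (means - mean(y))^2)
  ssw <- sum((y - means[f])^2)
  df1 <- k - 1; df2 <- N - k
  if (ssb <= .Machine$double.eps * sum(y^2)) {
    fstat <- 0; p <- 1
  } else if (ssw <= 0) {
    fstat <- Inf; p <- 0
  } else {
    fstat <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  }
  sp <- if (df2 > 0) sqrt(ssw / df2) else 0
  tq <- stats::qt(1 - alpha / 2, max(df2, 1))
  summaries <- data.frame(
    level = names(means), n = as.integer(ns),
    mean_fd = as.numeric(means),
    ci_low = as.numeric(means) - tq * sp / sqrt(as.integer(ns)),
    ci_high = as.numeric(means) + tq * sp / sqrt(as.integer(ns)),
    row.names = NULL)
  list(summaries = summaries, f_statistic = fstat, df = c(df1, df2),
       p_value = p)
}

#' Two-factor interaction model for fractal dimension
#'
#' Fits the linear model `fd ~ A * B` and reports the interaction-term
#' F-test (the sequential test of the interaction entered last, which for
#' the highest-order term coincides with the marginal test), together with
#' cell means and pooled-variance confidence intervals.
#'
#' @param cohort a `cohort_table`.
#' @param factor_a,factor_b grouping column names (e.g. diabetes, gender).
#' @param alpha error level for the cell intervals.
#' @return A list with `cells` (data.frame: level_a, level_b, n, mean_fd,
#'   ci_low, ci_high), `interaction_p`, and the fitted `model`.
#' @export
interaction_anova <- function(cohort, factor_a = "diabetes",
                              factor_b = "gender", alpha = 0.05) {
  .check_cohort(cohort, c("fd", factor_a, factor_b))
  A <- factor(cohort[[factor_a]]); B <- factor(cohort[[factor_b]])
  ns <- table(A, B)
  if (any(ns == 0))
    rf_stop("rf_stats_error", "empty cell in %s x %s", factor_a, factor_b)
  fit <- stats::lm(cohort$fd ~ A * B)
  an <- stats::anova(fit)
  interaction_p <- an[["Pr(>F)"]][rownames(an) == "A:B"]
  cellmean <- tapply(cohort$fd, list(A, B), mean)
  df2 <- fit$df.residual
  sp <- sqrt(sum(stats::residuals(fit)^2) / df2)
  tq <- stats::qt(1 - alpha / 2, df2)
  grid <- expand.grid(level_a = levels(A), level_b = levels(B),
                      stringsAsFactors = FALSE)
  cells <- data.frame(
    grid,
    n = as.integer(ns[cbind(grid$level_a, grid$level_b)]),
    mean_fd = cellmean[cbind(grid$level_a, grid$level_b)],
    row.names = NULL)
  cells$ci_low <- cells$mean_fd - tq * sp / sqrt(cells$n)
  cells$ci_high <- cells$mean_fd + tq * sp / sqrt(cells$n)
  list(cells = cells, interaction_p = unname(interaction_p), model = fit)
}

#' Multivariate OLS model of fractal dimension
#'
#' Ordinary least squares of FD on BMI, age, systolic and diastolic blood
#' pressure, gender (female = 1) and diabetes status, after an inclusive
#' age filter.  `age_min = 14, age_max = 73` is the full-population model;
#' `age_min = 50` reproduces the age-restricted model.
#'
#' @param cohort a `cohort_table`.
#' @param age_min,age_max inclusive age limits applied before fitting.
#' @return A list of class `rf_regression` with `coefficients` (data.frame:
#'   term, estimate, se, p_value), `r_squared`, `r_squared_adj`, `n`, and
#'   the fitted `model`.
#' @export
ols_regression <- function(cohort, age_min = 14, age_max = 73) {
  .check_cohort(cohort, c("fd", "age", "gender", "bmi", "sbp", "dbp",
                          "diabetes"))
  keep <- cohort$age >= age_min & cohort$age <= age_max
  dat <- cohort[keep, , drop = FALSE]
  X <- data.frame(bmi = dat$bmi, age = dat$age, sbp = dat$sbp, dbp = dat$dbp,
                  gender = as.numeric(dat$gender == "female"),
                  diabetes = as.numeric(dat$diabetes))
  rf_assert(nrow(dat) > ncol(X) + 1, "rf_stats_error",
            "only %d subjects after the age filter; need more than %d",
            nrow(dat), ncol(X) + 1)
  mm <- cbind(`(Intercept)` = 1, as.matrix(X))
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    piv <- colnames(mm)[qrm$pivot[-seq_len(qrm$rank)]]
    rf_stop("rf_stats_error", "rank-deficient design; collinear column(s): %s",
            paste(piv, collapse = ", "))
  }
  fit <- stats::lm(dat$fd ~ ., data = X)
  sm <- summary(fit)
  co <- sm$coefficients
  res <- list(
    coefficients = data.frame(term = rownames(co),
                              estimate = co[, 1], se = co[, 2],
                              p_value = co[, 4], row.names = NULL),
    r_squared = sm$r.squared,
    r_squared_adj = sm$adj.r.squared,
    n = nrow(dat),
    model = fit)
  class(res) <- "rf_regression"
  res
}

#' @export
print.rf_regression <- function(x, ...) {
  cat(sprintf("<rf_regression> n = %d, R^2 = %.3f (adj %.3f)\n",
              x$n, x$r_squared, x$r_squared_adj))
  print(format(x$coefficients, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Full cohort report
#'
#' Runs the study's statistical layer on a cohort: normality of FD,
#' one-way ANOVA by diabetes and by gender, the diabetes x gender
#' interaction, and the requested OLS model.
#'
#' @param cohort a `cohort_table`.
#' @param model 1 (full age range 14-73) or 2 (ages 50-73).
#' @param age_min,age_max optional explicit overrides of the model's age
#'   window.
#' @return A named list mirroring the report structure: `normality`,
#'   `anova_diabetes`, `anova_gender`, `interaction`, `regression`.
#' @export
cohort_report <- function(cohort, model = 1, age_min = NULL, age_max = NULL) {
  rf_assert(model %in% c(1, 2), "rf_param_error", "model must be 1 or 2")
  if (is.null(age_min)) age_min <- if (model == 1) 14 else 50
  if (is.null(age_max)) age_max <- 73
  list(normality = anderson_darling_normality(cohort$fd),
       anova_diabetes = group_anova(cohort, "diabetes"),
       anova_gender = group_anova(cohort, "gender"),
       interaction = interaction_anova(cohort, "diabetes", "gender"),
       regression = ols_regression(cohort, age_min, age_max))
}
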