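test_that("normality testing behaves under null and alternative", {
  set.seed(14)
  nrm <- anderson_darling_normality(rnorm(5000))
  expect_gt(nrm$p_value, 0.01)
  unif <- anderson_darling_normality(runif(5000))
  expect_lt(unif$p_value, 0.01)
  expect_rf_error(anderson_darling_normality(c(1, 2, 3)), "rf_stats_error")
  expect_rf_error(anderson_darling_normality(rep(1, 50)), "rf_stats_error")
})

test_that("mean_ci gives symmetric t intervals with the right width", {
  ci <- mean_ci(c(1, 2, 3))
  expect_equal(ci$mean, 2)
  expect_equal(ci$mean - ci$ci_low, ci$ci_high - ci$mean)
  set.seed(3)
  x <- rnorm(10000)
  ci <- mean_ci(x)
  expect_lt(abs((ci$ci_high - ci$ci_low) / 2 - 1.96 / sqrt(10000)) /
              (1.96 / sqrt(10000)), 0.10)
  expect_rf_error(mean_ci(5), "rf_stats_error")
})

test_that("two-level ANOVA reproduces the pooled t-test exactly", {
  set.seed(21)
  for (k in 1:5) {
    ch <- gen_cohort(cohort_gen_params(n_control = sample(10:40, 1),
                                       n_case = sample(5:20, 1),
                                       seed = k), mode = "group_mean")
    res <- group_anova(ch, "diabetes")
    tt <- t.test(fd ~ diabetes, data = ch, var.equal = TRUE)
    expect_equal(res$p_value, tt$p.value, tolerance = 1e-9)
    expect_equal(res$f_statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  }
})

test_that("ANOVA handles degenerate groups as specified", {
  ch <- data.frame(fd = rep(2.4, 20), diabetes = rep(c(0, 1), each = 10))
  res <- group_anova(ch, "diabetes")
  expect_equal(res$f_statistic, 0)
  expect_equal(res$p_value, 1)

  ch2 <- data.frame(fd = rnorm(5, 2.4, 0.01), diabetes = c(0, 0, 0, 0, 1))
  expect_rf_error(group_anova(ch2, "diabetes"), "rf_stats_error")
  ch3 <- data.frame(fd = rnorm(5, 2.4, 0.01), diabetes = rep(1, 5))
  expect_rf_error(group_anova(ch3, "diabetes"), "rf_stats_error")
})

test_that("group summaries use pooled-variance confidence intervals", {
  set.seed(9)
  ch <- gen_cohort(cohort_gen_params(seed = 9), mode = "group_mean")
  res <- group_anova(ch, "diabetes")
  s <- res$summaries
  expect_true(all(s$ci_low <= s$mean_fd & s$mean_fd <= s$ci_high))
  # interval half-widths scale as 1/sqrt(n) with a common variance
  hw <- (s$ci_high - s$ci_low) / 2
  expect_equal(hw[1] / hw[2], sqrt(s$n[2] / s$n[1]), tolerance = 1e-9)
})

test_that("the diabetes-gender interaction model reports cells and the test", {
  set.seed(33)
  # additive truth: males higher, diabetics higher, no interaction
  n <- 400
  gender <- factor(sample(c("female", "male"), n, TRUE),
                   levels = c("female", "male"))
  diabetes <- rbinom(n, 1, 0.3)
  fd <- 2.42 + 0.005 * (gender == "male") + 0.01 * diabetes +
    rnorm(n, 0, 0.012)
  ch <- data.frame(fd = fd, gender = gender, diabetes = diabetes)
  res <- interaction_anova(ch, "diabetes", "gender")
  cells <- res$cells
  for (lv in unique(cells$level_a)) {
    sub <- cells[cells$level_a == lv, ]
    expect_gt(sub$mean_fd[sub$level_b == "male"],
              sub$mean_fd[sub$level_b == "female"])
  }
  expect_gt(res$interaction_p, 0.001)

  ch_bad <- ch[!(ch$diabetes == 1 & ch$gender == "female"), ]
  expect_rf_error(interaction_anova(ch_bad, "diabetes", "gender"),
                  "rf_stats_error")
})

test_that("a null interaction is rejected at roughly the nominal rate", {
  set.seed(55)
  rej <- 0; nrep <- 300
  for (k in seq_len(nrep)) {
    n <- 120
    gender <- factor(sample(c("female", "male"), n, TRUE),
                     levels = c("female", "male"))
    diabetes <- rbinom(n, 1, 0.3)
    fd <- 2.42 + 0.004 * (gender == "male") + 0.008 * diabetes +
      rnorm(n, 0, 0.015)
    ch <- data.frame(fd = fd, gender = gender, diabetes = diabetes)
    p <- tryCatch(interaction_anova(ch, "diabetes", "gender")$interaction_p,
                  rf_stats_error = function(e) NA_real_)
    if (!is.na(p) && p < 0.05) rej <- rej + 1
  }
  expect_gt(rej / nrep, 0.015)
  expect_lt(rej / nrep, 0.10)
})

test_that("noise-free cohorts are recovered exactly by the regression", {
  p <- cohort_gen_params(fd_noise_sd = 0, seed = 17)
  ch <- gen_cohort(p, mode = "regression")
  res <- suppressWarnings(ols_regression(ch))   # lm warns on a perfect fit
  est <- setNames(res$coefficients$estimate, res$coefficients$term)
  truth <- p$fd_coefficients
  expect_equal(unname(est["(Intercept)"]), unname(truth["constant"]),
               tolerance = 1e-9)
  for (nm in c("bmi", "age", "sbp", "dbp", "gender", "diabetes"))
    expect_equal(unname(est[nm]), unname(truth[nm]), tolerance = 1e-9)
  expect_equal(res$r_squared, 1, tolerance = 1e-9)
})

test_that("regression guards its design matrix and age filter", {
  ch <- gen_cohort(cohort_gen_params(seed = 4))
  ch$sbp <- ch$dbp   # duplicate predictor
  err <- tryCatch(ols_regression(ch), error = function(e) e)
  expect_s3_class(err, "rf_stats_error")
  expect_match(conditionMessage(err), "collinear")

  ch2 <- gen_cohort(cohort_gen_params(seed = 4))
  ch2$age[1:2] <- c(50, 73)     # exactly on the window boundaries
  res <- ols_regression(ch2, age_min = 50, age_max = 73)
  expect_identical(res$n, sum(ch2$age >= 50 & ch2$age <= 73))
  expect_lte(res$r_squared_adj, res$r_squared)

  few <- ch2[1:6, ]
  expect_rf_error(ols_regression(few), "rf_stats_error")
})

test_that("the full cohort report runs both models end to end", {
  ch <- gen_cohort(cohort_gen_params(seed = 28), mode = "regression")
  rep1 <- cohort_report(ch, model = 1)
  rep2 <- cohort_report(ch, model = 2)
  expect_named(rep1, c("normality", "anova_diabetes", "anova_gender",
                       "interaction", "regression"))
  expect_lt(rep2$regression$n, rep1$regression$n)
  expect_true(all(ch$fd >= 2 & ch$fd <= 3))
})
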