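test_that("all generators are pure functions of their seed", {
  expect_identical(gen_fbm_surface(0.5, 128, 42)$pixels,
                   gen_fbm_surface(0.5, 128, 42)$pixels)
  a <- gen_synthetic_fundus(small_fundus_params(seed = 42))
  b <- gen_synthetic_fundus(small_fundus_params(seed = 42))
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$vessel_mask, b$vessel_mask)
  expect_identical(gen_cohort(cohort_gen_params(seed = 42)),
                   gen_cohort(cohort_gen_params(seed = 42)))
  # generators do not disturb the caller's RNG stream
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(gen_fbm_surface(0.5, 64, 9)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("fractional Brownian surfaces get rougher as the Hurst exponent drops", {
  lap_var <- function(img) {
    m <- img$pixels
    h <- nrow(m); w <- ncol(m)
    core <- m[2:(h - 1), 2:(w - 1)]
    lap <- m[1:(h - 2), 2:(w - 1)] + m[3:h, 2:(w - 1)] +
      m[2:(h - 1), 1:(w - 2)] + m[2:(h - 1), 3:w] - 4 * core
    stats::var(as.numeric(lap))
  }
  v_rough <- lap_var(gen_fbm_surface(0.1, 256, 7))
  v_smooth <- lap_var(gen_fbm_surface(0.9, 256, 7))
  expect_lt(v_smooth, v_rough)

  fds <- sapply(c(0.2, 0.5, 0.8), function(H)
    mean(sapply(1:5, function(s) dbc_fd(gen_fbm_surface(H, 256, s))$fd)))
  expect_true(all(diff(fds) < 0))
})

test_that("the synthesised spectrum has the prescribed power-law slope", {
  for (H in c(0.3, 0.6)) {
    slopes <- sapply(1:5, function(s)
      periodogram_slope(gen_fbm_surface(H, 256, s)))
    expect_lt(abs(mean(slopes) - (-(2 * H + 2))), 0.3)
  }
})

test_that("fBm parameter validation rejects invalid input", {
  expect_rf_error(gen_fbm_surface(0, 128, 1), "rf_param_error")
  expect_rf_error(gen_fbm_surface(0.5, 100, 1), "rf_param_error")
  expect_rf_error(gen_fbm_surface(0.5, 32, 1), "rf_param_error")
})

test_that("an unperturbed depth-1 tree is two straight trunks of root width", {
  p <- synth_fundus_params(height = 640L, width = 960L, od_diameter = 120,
                           branch_depth = 1L, root_width = 10,
                           tortuosity_amp = 0, background_noise_sd = 0,
                           seed = 3)
  sf <- gen_synthetic_fundus(p)
  # mask width measured across the trunk halfway down each root
  for (off in c(-53, 53)) {
    widths <- rowSums(sf$vessel_mask[320 + off + (-2:2), ])
    expect_true(all(abs(widths - 10) <= 1.5))
  }
  # two trunks only: nothing drawn left/right of the disc column band
  expect_equal(sum(sf$vessel_mask[, c(1:380, 580:960)]), 0)
})

test_that("a featureless parameterisation yields a constant image", {
  p <- synth_fundus_params(height = 128L, width = 128L, od_diameter = 0,
                           branch_depth = 0L, background_noise_sd = 0,
                           seed = 1)
  sf <- gen_synthetic_fundus(p)
  for (ch in 1:3)
    expect_equal(length(unique(as.vector(sf$image$pixels[, , ch]))), 1)
})

test_that("a tree that cannot fit the frame raises a geometry error", {
  p <- synth_fundus_params(height = 640L, width = 960L,
                           od_center = c(30, 480), od_diameter = 40, seed = 1)
  expect_rf_error(gen_synthetic_fundus(p), "rf_geometry_error")
})

test_that("noise-free cohorts reproduce the generating model exactly", {
  p <- cohort_gen_params(fd_noise_sd = 0,
                         fd_coefficients = c(constant = 2.43, bmi = 0,
                                             age = 0, sbp = 0, dbp = 0,
                                             gender = 0, diabetes = 0),
                         seed = 8)
  ch <- gen_cohort(p, mode = "regression")
  expect_true(all(ch$fd == 2.43))
  expect_identical(nrow(ch), 189L)
  expect_identical(sum(ch$diabetes), 23L)
})

test_that("cohort marginals converge to the requested distributions", {
  p <- cohort_gen_params(n_control = 10000L, n_case = 10000L, seed = 12)
  ch <- gen_cohort(p, mode = "regression")
  ctl <- ch[ch$diabetes == 0, ]
  cas <- ch[ch$diabetes == 1, ]
  # untruncated covariates: within 2% of the requested moments
  expect_lt(abs(mean(ctl$bmi) - 24.49) / 24.49, 0.02)
  expect_lt(abs(sd(ctl$sbp) - 15.81) / 15.81, 0.02)
  expect_lt(abs(mean(cas$sbp) - 143.04) / 143.04, 0.02)
  expect_lt(abs(mean(cas$gender == "female") - 12 / 23), 0.02)
  # ages follow the truncated-normal moments for the 14-73 window
  tmoments <- function(mu, sig, lo, hi) {
    a <- (lo - mu) / sig; b <- (hi - mu) / sig
    Z <- pnorm(b) - pnorm(a)
    m <- mu + sig * (dnorm(a) - dnorm(b)) / Z
    v <- sig^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                    ((dnorm(a) - dnorm(b)) / Z)^2)
    c(m, sqrt(v))
  }
  tm <- tmoments(32.50, 13.60, 14, 73)
  expect_lt(abs(mean(ctl$age) - tm[1]) / tm[1], 0.02)
  expect_lt(abs(sd(ctl$age) - tm[2]) / tm[2], 0.02)
  expect_true(all(ch$age >= 14 & ch$age <= 73))
})

test_that("case covariates and group means match the study population", {
  ch <- gen_cohort(cohort_gen_params(seed = 31), mode = "group_mean")
  cas <- ch[ch$diabetes == 1, ]
  # sample case-age mean within 2 SE of the published 52.69 (SD 7.90)
  expect_lt(abs(mean(cas$age) - 52.69), 2 * 7.90 / sqrt(23))
  ctl <- ch[ch$diabetes == 0, ]
  expect_lt(abs(mean(ctl$fd) - 2.4227), 3 * 0.01676 / sqrt(166))
  expect_lt(abs(mean(cas$fd) - 2.4403), 3 * 0.01664 / sqrt(23))
})

test_that("cohort CSV round trip preserves the table", {
  ch <- gen_cohort(cohort_gen_params(n_control = 20L, n_case = 5L, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(ch, path)
  back <- read_cohort_csv(path)
  expect_equal(back$fd, ch$fd, tolerance = 1e-12)
  expect_identical(back$gender, ch$gender)
  expect_identical(names(back), names(ch))
})

test_that("the validation image suite is diverse and deterministic", {
  suite <- gen_image_suite(seed = 3, n = 12L)
  expect_length(suite, 12L)
  kinds <- vapply(suite, function(x) attr(x, "kind"), character(1))
  expect_setequal(unique(kinds), c("constant", "noise", "gradient", "fbm",
                                   "enhanced_roi"))
  suite2 <- gen_image_suite(seed = 3, n = 12L)
  expect_identical(suite[[12]]$pixels, suite2[[12]]$pixels)
})
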