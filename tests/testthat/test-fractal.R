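test_that("per-cell box counts follow the difference formula", {
  expect_identical(dbc_cell_count(5, 5, 7), 1L)
  expect_identical(dbc_cell_count(0, 3, 2), 2L)
  expect_identical(dbc_cell_count(0, 255, 1), 256L)
  expect_identical(dbc_cell_count(c(0, 5), c(3, 5), 2), c(2L, 1L))
  expect_rf_error(dbc_cell_count(7, 3, 2), "rf_logic_error")
  expect_rf_error(dbc_cell_count(0, 3, 0), "rf_param_error")
})

test_that("grid counts match the hand-worked 4x4 example", {
  img <- matrix(c(0, 1, 2, 3,
                  1, 1, 2, 2,
                  3, 2, 1, 0,
                  0, 0, 3, 3), 4, 4, byrow = TRUE)
  expect_equal(dbc_grid_counts(img, 2, G = 4), 6)
})

test_that("grid counts agree exactly with the brute-force oracle", {
  set.seed(101)
  for (k in 1:25) {
    sz <- sample(c(8L, 16L), 1)
    m <- matrix(sample(0:255, sz * sz, replace = TRUE), sz, sz)
    for (s in c(2, 4, sz / 2))
      expect_identical(dbc_grid_counts(m, s, G = 256),
                       brute_force_dbc(m, s, 256))
  }
  # non-square with partial boundary cells
  m <- matrix(sample(0:255, 10 * 13, replace = TRUE), 10, 13)
  for (s in c(2, 4))
    expect_identical(dbc_grid_counts(m, s, G = 256),
                     brute_force_dbc(m, s, 256))
})

test_that("constant and near-trivial images hit the analytic values", {
  cv <- dbc_fd(matrix(100L, 256, 256))
  expect_equal(cv$fd, 2, tolerance = 1e-9)
  expect_equal(cv$r_squared, 1, tolerance = 1e-9)
  expect_equal(dbc_grid_counts(matrix(5L, 8, 8), 2, G = 256), 16)
  # s = M/2 always yields at least four cells
  expect_gte(dbc_grid_counts(matrix(sample(0:255, 64^2, TRUE), 64, 64), 32), 4)
})

test_that("the estimate is exactly invariant to constant offsets", {
  set.seed(5)
  m <- matrix(sample(0:200, 128 * 128, replace = TRUE), 128, 128)
  expect_identical(dbc_fd(m)$fd, dbc_fd(m + 55L)$fd)
  fb <- gen_fbm_surface(0.5, 128, 9)
  capped <- pmin(fb$pixels, 225L)            # leave headroom for the shift
  expect_identical(dbc_fd(capped)$fd, dbc_fd(capped + 30L)$fd)
})

test_that("estimates stay within the theoretical surface bounds", {
  set.seed(77)
  imgs <- list(
    matrix(0L, 64, 64),
    matrix(sample(0:255, 64^2, TRUE), 64, 64),
    outer(1:128, 1:128, function(i, j) as.integer(round((i + j) / 256 * 255))),
    gen_fbm_surface(0.3, 128, 1)$pixels,
    gen_fbm_surface(0.7, 128, 2)$pixels)
  for (m in imgs) {
    fd <- dbc_fd(m)$fd
    expect_gte(fd, 2 - 1e-9)
    expect_lte(fd, 3 + 1e-9)
    # the fixed-partition variant tracks the difference-based default
    # closely but is not offset-free, so it gets a tolerance, not the bound
    fd_abs <- dbc_fd(m, variant = "absolute")$fd
    expect_lt(abs(fd_abs - fd), 0.1)
  }
})

test_that("too few usable scales raise a configuration error", {
  expect_rf_error(dbc_fd(matrix(0L, 64, 64), min_s = 16, max_s = 32),
                  "rf_config_error")
  expect_rf_error(grid_scales(64, max_s = 64), "rf_config_error")
})

test_that("binary box counting matches known sets", {
  expect_equal(binary_bc_fd(matrix(1L, 256, 256))$fd, 2, tolerance = 1e-9)
  line <- matrix(0L, 256, 256); line[100, ] <- 1L
  expect_equal(binary_bc_fd(line)$fd, 1, tolerance = 0.05)
  pt <- matrix(0L, 256, 256); pt[31, 57] <- 1L
  expect_equal(binary_bc_fd(pt)$fd, 0, tolerance = 1e-9)
  expect_rf_error(binary_bc_fd(matrix(0L, 64, 64)), "rf_input_error")
})

test_that("percentile segmentation separates classes and rejects constants", {
  mask <- matrix(FALSE, 64, 64); mask[, 1:32] <- TRUE
  two <- gray_image(matrix(ifelse(mask, 255L, 0L), 64, 64))
  expect_identical(segment_vessels(two, 50), mask)
  expect_rf_error(segment_vessels(gray_image(matrix(9L, 64, 64)), 85),
                  "rf_segmentation_error")
  expect_rf_error(segment_vessels(two, 0), "rf_param_error")
  expect_rf_error(segment_vessels(two, 100), "rf_param_error")
})

test_that("segmentation of enhanced synthetic ROIs overlaps the true vessels", {
  dice <- numeric(3)
  for (s in 1:3) {
    sf <- gen_synthetic_fundus(small_fundus_params(seed = s + 20))
    roi <- extract_roi(extract_green_inverted(sf$image), sf$od_truth,
                       small_roi_spec())
    en <- enhance_vessels(roi)
    mk <- roi_mask(sf$vessel_mask, sf$od_truth)
    seg <- segment_vessels(en, 85)
    dice[s] <- 2 * sum(seg & mk) / (sum(seg) + sum(mk))
    # the comparator route: binary box-count of the segmented vessels
    bc <- binary_bc_fd(seg)
    expect_gt(bc$fd, 1)
    expect_lt(bc$fd, 2)
  }
  expect_gt(mean(dice), 0.55)
})

test_that("box-count curves serialise losslessly enough to re-read", {
  cv <- dbc_fd(gen_fbm_surface(0.5, 128, 4))
  pj <- withr::local_tempfile(fileext = ".json")
  write_curve(cv, pj, "json")
  js <- jsonlite::fromJSON(pj)
  expect_equal(js$fd, cv$fd)
  expect_equal(js$N_r, cv$counts)
  pc <- withr::local_tempfile(fileext = ".csv")
  write_curve(cv, pc, "csv")
  lines <- readLines(pc)
  expect_identical(lines[1], "s,r,N_r")
  expect_true(any(grepl("^# fd,", lines)))
})
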