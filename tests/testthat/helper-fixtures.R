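# shared helpers: small geometries keep the per-test cost low; the
# full-size study geometry is exercised in test-acceptance.R

# compact fundus scene for pipeline-level tests
small_fundus_params <- function(seed = 1L, ...) {
  synth_fundus_params(height = 640L, width = 960L, od_diameter = 120,
                      root_width = 10, seed = seed, ...)
}

small_roi_spec <- function() roi_spec(out_height = 256L, out_width = 256L)

# transform a full-frame vessel mask into the ROI frame
roi_mask <- function(mask, od, spec = small_roi_spec()) {
  g <- gray_image(matrix(as.integer(mask) * 255L, nrow(mask), ncol(mask)))
  extract_roi(g, od, spec)$pixels > 127
}

# independent brute-force oracle for per-scale differential box counts
brute_force_dbc <- function(m, s, G) {
  M <- min(dim(m)); sp <- s * G / M
  n <- 0
  for (i in seq(1, nrow(m), by = s)) {
    for (j in seq(1, ncol(m), by = s)) {
      cell <- m[i:min(i + s - 1, nrow(m)), j:min(j + s - 1, ncol(m))]
      n <- n + floor((max(cell) - min(cell)) / sp) + 1
    }
  }
  as.integer(n)
}

# brute-force spatial response of one complex Gabor kernel at one pixel
brute_force_gabor_at <- function(img, scale, theta, elongation, at) {
  k <- retfractal:::.gabor_kernel(scale, theta, elongation)
  half <- (nrow(k) - 1) / 2
  rows <- (at[1] - half):(at[1] + half)
  cols <- (at[2] - half):(at[2] + half)
  stopifnot(min(rows) >= 1, max(rows) <= nrow(img),
            min(cols) >= 1, max(cols) <= ncol(img))
  # correlation with the conjugate == convolution modulus for these kernels
  patch <- img[rows, cols]
  Mod(sum(patch * k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k)))]))
}

expect_rf_error <- function(expr, class) {
  expect_error(expr, class = class)
}
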