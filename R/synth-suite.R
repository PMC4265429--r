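#' Seeded suite of diverse grayscale test images
#'
#' Builds the validation suite used to exercise the theoretical bounds of
#' the grayscale box-counting estimator: constant images, uniform noise,
#' linear gradients of random orientation, fractional Brownian surfaces at
#' Hurst exponents 0.2/0.5/0.8, and enhanced synthetic retinal regions of
#' interest.  Sizes span 128-512 px.  Deterministic in `seed`.
#'
#' @param seed integer RNG seed.
#' @param n total number of images (allocated roughly 10% constant,
#'   25% noise, 20% gradient, 30% fBm, 15% enhanced ROI).
#' @return A list of [gray_image()] objects with a `kind` attribute each.
#' @export
gen_image_suite <- function(seed = 1L, n = 100L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_const <- round(0.10 * n); n_noise <- round(0.25 * n)
  n_grad <- round(0.20 * n); n_fbm <- round(0.30 * n)
  n_roi <- n - n_const - n_noise - n_grad - n_fbm
  sizes <- c(128L, 256L, 512L)
  out <- vector("list", n)
  i <- 0L
  add <- function(img, kind) {
    i <<- i + 1L
    attr(img, "kind") <- kind
    out[[i]] <<- img
  }
  for (k in seq_len(n_const)) {
    sz <- sample(sizes, 1)
    add(gray_image(matrix(sample(0:255, 1), sz, sz)), "constant")
  }
  for (k in seq_len(n_noise)) {
    sz <- sample(sizes, 1)
    add(gray_image(matrix(sample(0:255, sz * sz, replace = TRUE), sz, sz)),
        "noise")
  }
  for (k in seq_len(n_grad)) {
    sz <- sample(sizes, 1)
    th <- stats::runif(1, 0, 2 * pi)
    g <- outer(seq_len(sz) * sin(th), seq_len(sz) * cos(th), "+")
    g <- (g - min(g)) / (max(g) - min(g))
    add(gray_image(matrix(as.integer(round(g * 255)), sz, sz)), "gradient")
  }
  hs <- rep(c(0.2, 0.5, 0.8), length.out = n_fbm)
  for (k in seq_len(n_fbm)) {
    sz <- sample(sizes, 1)
    add(gen_fbm_surface(hs[k], sz, seed = sample.int(2^30, 1)), "fbm")
  }
  for (k in seq_len(n_roi)) {
    sf <- gen_synthetic_fundus(synth_fundus_params(
      height = 640L, width = 960L, od_diameter = 120, root_width = 10,
      seed = sample.int(2^30, 1)))
    roi <- extract_roi(extract_green_inverted(sf$image), sf$od_truth,
                       roi_spec(out_height = 256L, out_width = 256L))
    add(enhance_vessels(roi), "enhanced_roi")
  }
  out
}
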