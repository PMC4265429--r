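#' Fractional Brownian surface by spectral synthesis
#'
#' Generates a random self-affine surface with Hurst exponent `H` by
#' filtering complex Gaussian white noise with an isotropic spectral
#' amplitude proportional to `f^-(H+1)` (power `f^-(2H+2)`), inverse
#' Fourier transforming, and linearly quantising the real part to
#' `[0, 255]`.  The theoretical fractal dimension of such a surface is
#' `3 - H`, which makes these fields the estimator oracle for [dbc_fd()].
#' Output is a pure function of `(hurst, size, seed)`.
#'
#' @param hurst Hurst exponent in (0, 1); smaller is rougher.
#' @param size square side length in pixels; a power of two, at least 64.
#' @param seed integer RNG seed.
#' @return A [gray_image()] of dimension `size x size`.
#' @export
gen_fbm_surface <- function(hurst, size = 512L, seed = 1L) {
  rf_assert(hurst > 0 && hurst < 1, "rf_param_error", "hurst must be in (0,1)")
  rf_assert(size >= 64 && bitwAnd(size, size - 1L) == 0, "rf_param_error",
            "size must be a power of two >= 64")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  w <- matrix(stats::rnorm(size * size), size, size)
  W <- stats::fft(w)
  f1 <- 0:(size - 1)
  f1 <- ifelse(f1 > size / 2, f1 - size, f1)
  FX <- matrix(f1, size, size)
  f <- sqrt(FX^2 + t(FX)^2)
  f[1, 1] <- 1
  amp <- f^(-(hurst + 1))
  amp[1, 1] <- 0                      # remove DC; mean handled by quantiser
  z <- Re(stats::fft(W * amp, inverse = TRUE)) / (size * size)
  q <- (z - min(z)) / (max(z) - min(z))
  gray_image(matrix(as.integer(round(q * 255)), size, size), 256L)
}

# preserve the caller's RNG state so generators are side-effect free
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
}

#' Radially averaged log-periodogram slope
#'
#' Diagnostic used to verify the spectral content of generated surfaces:
#' fits the slope of mean log power against log radial frequency over the
#' mid-frequency band.  For a surface with Hurst exponent `H` the expected
#' slope is `-(2H + 2)`.
#'
#' @param img a [gray_image()] (square).
#' @param band fraction range of the Nyquist frequency to fit over.
#' @return The fitted slope (numeric).
#' @export
periodogram_slope <- function(img, band = c(0.03, 0.3)) {
  m <- if (inherits(img, "gray_image")) img$pixels else img
  n <- nrow(m)
  P <- Mod(stats::fft(m - mean(m)))^2
  f1 <- 0:(n - 1)
  f1 <- ifelse(f1 > n / 2, f1 - n, f1)
  FX <- matrix(f1, n, n)
  f <- sqrt(FX^2 + t(FX)^2)
  sel <- f >= band[1] * (n / 2) & f <= band[2] * (n / 2)
  # average the periodogram within logarithmic frequency rings
  lf <- log(f[sel]); lp <- P[sel]
  br <- seq(min(lf), max(lf), length.out = 25)
  bin <- findInterval(lf, br, rightmost.closed = TRUE)
  mp <- tapply(lp, bin, mean)
  mf <- tapply(lf, bin, mean)
  .ols_line(as.numeric(mf), log(as.numeric(mp)))$slope
}
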