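# Optic disc detection: initialise from the brightest red-channel blob,
# refine with a radial active contour on the gradient-magnitude edge map,
# fall back to an exhaustive circle search when the contour fails.

# bilinear sample of matrix m at real-valued (row, col); clamped at borders
.interp2 <- function(m, r, c) {
  h <- nrow(m); w <- ncol(m)
  r <- pmin(pmax(r, 1), h); c <- pmin(pmax(c, 1), w)
  r0 <- pmin(floor(r), h - 1); c0 <- pmin(floor(c), w - 1)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

# gradient magnitude by central differences (border rows/cols replicated)
.grad_mag <- function(m) {
  h <- nrow(m); w <- ncol(m)
  gy <- (m[c(2:h, h), ] - m[c(1, 1:(h - 1)), ]) / 2
  gx <- (m[, c(2:w, w)] - m[, c(1, 1:(w - 1))]) / 2
  sqrt(gy^2 + gx^2)
}

#' Detect the optic disc
#'
#' Locates the bright, roughly circular optic disc on the RGB image.  The
#' contour is initialised from the centroid of the largest connected
#' component of the brightest 2% of (smoothed) red-channel pixels, then
#' evolved as a radial active contour that balances edge attraction against
#' boundary smoothness (iteration cap 500, movement tolerance 0.1 px).  If
#' the contour does not converge, an exhaustive circle search over nearby
#' centres and radii on the edge map is used instead.  A least-squares
#' circle is fitted to the final boundary.
#'
#' @param img a [fundus_image()].
#' @param n_points number of contour points.
#' @param max_iter iteration cap for the contour evolution.
#' @param tol convergence tolerance on point movement, in pixels.
#' @param min_contrast minimum gray-level difference between the bright
#'   candidate region and the image median; below this the image is rejected
#'   as having no detectable disc (the exclusion signal for ungradable
#'   photographs).
#' @return An [optic_disc()].
#' @export
detect_od <- function(img, n_points = 72L, max_iter = 500L, tol = 0.1,
                      min_contrast = 15) {
  stopifnot(inherits(img, "fundus_image"))
  red <- img$pixels[, , 1]
  h <- nrow(red); w <- ncol(red)
  red_s <- EBImage::gblur(red, sigma = 2)

  med <- stats::median(red_s)
  if (max(red_s) - med < min_contrast)
    rf_stop("rf_detection_error",
            "no bright candidate region above the initialisation threshold")
  # halfway between the background (median) and the brightest structure:
  # insensitive to how much of the frame the disc occupies
  thr <- med + 0.5 * (max(red_s) - med)

  lab <- EBImage::bwlabel(red_s >= thr)
  sizes <- tabulate(lab[lab > 0])
  best <- which.max(sizes)
  if (sizes[best] < 20)
    rf_stop("rf_detection_error", "bright candidate region too small")
  idx <- which(lab == best, arr.ind = TRUE)
  c0 <- colMeans(idx)                       # (row, col) centroid
  r0 <- sqrt(sizes[best] / pi)

  edge <- .grad_mag(EBImage::gblur(red, sigma = 3))
  edge <- edge / max(edge)

  theta <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  rho <- rep(r0 * 1.3, n_points)
  rho_max <- min(c0[1] - 1, h - c0[1], c0[2] - 1, w - c0[2], 3 * r0)
  rho <- pmin(rho, rho_max)
  beta <- 0.05     # smoothness weight (per px^2 of deviation from neighbours)
  pres <- 0.05     # balloon pressure (per px): pulls inward over flat regions
  deltas <- c(-1, -0.5, 0, 0.5, 1)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    nb_mean <- (rho[c(n_points, 1:(n_points - 1))] +
                rho[c(2:n_points, 1)]) / 2
    best_d <- numeric(n_points)
    best_e <- rep(Inf, n_points)
    for (d in deltas) {
      rr <- pmin(pmax(rho + d, 3), rho_max)
      e <- -.interp2(edge, c0[1] + rr * sin(theta), c0[2] + rr * cos(theta)) +
        beta * (rr - nb_mean)^2 + pres * rr
      upd <- e < best_e
      best_e[upd] <- e[upd]
      best_d[upd] <- rr[upd] - rho[upd]
    }
    rho <- rho + best_d
    if (max(abs(best_d)) < tol) { converged <- TRUE; break }
  }

  boundary <- cbind(row = c0[1] + rho * sin(theta),
                    col = c0[2] + rho * cos(theta))
  method <- "snake"

  ok <- converged && stats::sd(rho) < 0.5 * mean(rho)
  if (!ok) {
    # fallback: exhaustive search for the circle with the strongest mean edge
    cand_r <- seq(max(4, 0.5 * r0), max(8, 1.8 * r0), by = 1)
    cand_dy <- seq(-10, 10, by = 2); cand_dx <- cand_dy
    phi <- seq(0, 2 * pi, length.out = 61)[-61]
    best_score <- -Inf; best_c <- c0; best_r <- r0
    for (dy in cand_dy) for (dx in cand_dx) {
      cy <- c0[1] + dy; cx <- c0[2] + dx
      for (r in cand_r) {
        ry <- cy + r * sin(phi); rx <- cx + r * cos(phi)
        if (min(ry) < 1 || max(ry) > h || min(rx) < 1 || max(rx) > w) next
        sc <- mean(.interp2(edge, ry, rx))
        if (sc > best_score) { best_score <- sc; best_c <- c(cy, cx); best_r <- r }
      }
    }
    if (!is.finite(best_score) || best_score <= 0)
      rf_stop("rf_detection_error", "contour failed to converge and no circle found")
    boundary <- cbind(row = best_c[1] + best_r * sin(theta),
                      col = best_c[2] + best_r * cos(theta))
    method <- "hough"
  }

  fit <- fit_circle(boundary)
  if (fit$center[1] < 1 || fit$center[1] > h ||
      fit$center[2] < 1 || fit$center[2] > w)
    rf_stop("rf_detection_error", "fitted disc centre outside image bounds")
  optic_disc(fit$center, fit$diameter, boundary, fit$fit_rms, method)
}
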