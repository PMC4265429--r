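# Synthetic optic-disc-centred fundus images with ground truth: a reddish
# noisy background, a bright circular disc, and a recursive bifurcating
# vessel tree drawn dark on the green channel with Gaussian cross-sections.
# Deliberately minimal realism: enough structure to exercise disc detection,
# vessel enhancement and the fractal estimator with known truth.

#' Synthetic fundus parameters
#'
#' @param height,width image size in pixels.
#' @param od_center disc centre `(row, col)`; defaults to the image centre
#'   (the photographs being emulated are disc-centred).
#' @param od_diameter disc diameter in pixels; 0 suppresses the disc.
#' @param branch_depth bifurcation levels of the vessel tree; 0 suppresses
#'   vessels.
#' @param root_width root vessel width in pixels (at least 2 when vessels
#'   are drawn).
#' @param width_decay child/parent width ratio per bifurcation.
#' @param tortuosity_amp amplitude (pixels) of the sinusoidal centre-line
#'   perturbation; 0 gives straight segments.
#' @param background_noise_sd Gaussian background noise SD in gray levels.
#' @param seed integer RNG seed.
#' @return An object of class `synth_fundus_params`.
#' @export
synth_fundus_params <- function(height = 960L, width = 1440L,
                                od_center = NULL, od_diameter = 180,
                                branch_depth = 10L, root_width = 14,
                                width_decay = 0.88, tortuosity_amp = 3,
                                background_noise_sd = 14, seed = 1L) {
  if (is.null(od_center)) od_center <- c(height / 2, width / 2)
  if (od_diameter > 0) {
    r <- od_diameter / 2
    rf_assert(od_center[1] - r >= 1 && od_center[1] + r <= height &&
              od_center[2] - r >= 1 && od_center[2] + r <= width,
              "rf_geometry_error", "optic disc must lie fully inside the image")
  }
  rf_assert(branch_depth == 0 || root_width >= 2, "rf_param_error",
            "root_width must be at least 2")
  rf_assert(width_decay > 0 && width_decay <= 1, "rf_param_error",
            "width_decay must be in (0, 1]")
  rf_assert(background_noise_sd >= 0, "rf_param_error",
            "background_noise_sd must be non-negative")
  structure(list(height = as.integer(height), width = as.integer(width),
                 od_center = od_center, od_diameter = od_diameter,
                 branch_depth = as.integer(branch_depth),
                 root_width = root_width, width_decay = width_decay,
                 tortuosity_amp = tortuosity_amp,
                 background_noise_sd = background_noise_sd,
                 seed = as.integer(seed)),
            class = "synth_fundus_params")
}

# draw a Gaussian-profile tube along a polyline onto the intensity/mask
# canvases (environment-passed so recursion accumulates in place); the
# distance to the centre line is computed for the whole bounding box at
# once against centre-line samples spaced sigma/3 (profile ripple < 1%)
.draw_segment <- function(env, pts, width) {
  sigma <- width / 2.355                 # FWHM = width
  step <- max(1L, floor(sigma / 1.5))
  pts <- pts[unique(c(seq(1, nrow(pts), by = step), nrow(pts))), ,
             drop = FALSE]
  halfw <- max(2L, ceiling(2.5 * sigma))
  h <- nrow(env$V); w <- ncol(env$V)
  r0 <- max(1L, floor(min(pts[, 1]) - halfw))
  r1 <- min(h, ceiling(max(pts[, 1]) + halfw))
  c0 <- max(1L, floor(min(pts[, 2]) - halfw))
  c1 <- min(w, ceiling(max(pts[, 2]) + halfw))
  if (r0 > r1 || c0 > c1) return(invisible())
  rows <- r0:r1; cols <- c0:c1
  nr <- length(rows); nc <- length(cols)
  # min squared distance from every box pixel to the sampled centre line
  d2 <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(pts))) {
    dr2 <- (rows - pts[i, 1])^2
    dc2 <- (cols - pts[i, 2])^2
    keep_r <- dr2 <= (2.5 * halfw)^2
    if (!any(keep_r)) next
    d2[keep_r, ] <- pmin(d2[keep_r, ], outer(dr2[keep_r], dc2, "+"))
  }
  env$V[rows, cols] <- pmax(env$V[rows, cols], exp(-d2 / (2 * sigma^2)))
  env$mask[rows, cols] <- env$mask[rows, cols] | (d2 <= (width / 2)^2)
}

.grow_tree <- function(env, start, angle, width, len, depth, p) {
  if (depth > p$branch_depth) return(invisible())
  # prune once the branch has left the frame
  if (start[1] < 1 || start[1] > nrow(env$V) ||
      start[2] < 1 || start[2] > ncol(env$V)) return(invisible())
  tt <- seq(0, len, by = 0.5)
  dir <- c(sin(angle), cos(angle))
  nrm <- c(cos(angle), -sin(angle))
  wobble <- p$tortuosity_amp * sin(2 * pi * tt / max(len, 1) * 1.5 +
                                     env$phase[depth])
  pts <- cbind(start[1] + tt * dir[1] + wobble * nrm[1],
               start[2] + tt * dir[2] + wobble * nrm[2])
  .draw_segment(env, pts, width)
  endp <- pts[nrow(pts), ]
  if (depth < p$branch_depth) {
    spread <- stats::runif(1, 0.45, 0.75)
    jit <- stats::rnorm(2, 0, 0.15)
    for (sgn in c(-1, 1))
      .grow_tree(env, endp, angle + sgn * spread + jit[(sgn + 3) / 2],
                 width * p$width_decay, len * 0.9, depth + 1, p)
  }
}

#' Generate a synthetic fundus image with ground truth
#'
#' Renders a reddish noisy background, a bright optic disc with a smooth
#' edge, and a recursive bifurcating vessel tree rooted at the disc (two
#' primary vessels leaving vertically, bifurcating `branch_depth` times with
#' widths shrinking by `width_decay` and sinusoidal tortuosity), drawn dark
#' on the green channel with Gaussian cross-sections.
#'
#' @param p a [synth_fundus_params()].
#' @return A list with `image` (a [fundus_image()]), `od_truth` (an
#'   [optic_disc()] holding the true centre/diameter) and `vessel_mask`
#'   (logical matrix).
#' @export
gen_synthetic_fundus <- function(p = synth_fundus_params()) {
  stopifnot(inherits(p, "synth_fundus_params"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(p$seed)
  h <- p$height; w <- p$width

  base <- c(R = 175, G = 120, B = 55)
  ch <- lapply(base, function(b)
    matrix(b, h, w) + if (p$background_noise_sd > 0)
      matrix(stats::rnorm(h * w, 0, p$background_noise_sd), h, w) else 0)

  # vessel tree (drawn before the disc so the disc stays bright and clean
  # at its rim but vessels remain visible crossing it)
  env <- new.env()
  env$V <- matrix(0, h, w)
  env$mask <- matrix(FALSE, h, w)
  env$phase <- stats::runif(max(1, p$branch_depth), 0, 2 * pi)
  if (p$branch_depth >= 1) {
    root_len <- min(h, w) / 6
    for (ang in c(pi / 2, -pi / 2)) {     # superior and inferior trunks
      a <- ang + stats::rnorm(1, 0, 0.05)
      endp <- p$od_center + root_len * c(sin(a), cos(a))
      if (endp[1] < 1 || endp[1] > h || endp[2] < 1 || endp[2] > w)
        rf_stop("rf_geometry_error", "vessel tree leaves the image at depth 1")
      .grow_tree(env, p$od_center, a, p$root_width, root_len, 1L, p)
    }
  }
  ch$R <- ch$R * (1 - 0.35 * env$V)
  ch$G <- ch$G * (1 - 0.75 * env$V)
  ch$B <- ch$B * (1 - 0.20 * env$V)

  if (p$od_diameter > 0) {
    rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    d <- sqrt((rr - p$od_center[1])^2 + (cc - p$od_center[2])^2)
    wd <- 1 / (1 + exp((d - p$od_diameter / 2) / 1.5))   # smooth rim
    ch$R <- ch$R * (1 - wd) + 250 * wd
    ch$G <- ch$G * (1 - wd) + 215 * wd
    ch$B <- ch$B * (1 - wd) + 160 * wd
  }

  px <- array(0L, c(h, w, 3))
  for (i in 1:3)
    px[, , i] <- matrix(as.integer(pmin(pmax(round(ch[[i]]), 0), 255)), h, w)

  theta <- seq(0, 2 * pi, length.out = 73)[-73]
  truth <- optic_disc(
    center = c(row = p$od_center[1], col = p$od_center[2]),
    diameter = max(p$od_diameter, .Machine$double.eps),
    boundary = cbind(row = p$od_center[1] + p$od_diameter / 2 * sin(theta),
                     col = p$od_center[2] + p$od_diameter / 2 * cos(theta)),
    fit_rms = 0, method = "truth")

  list(image = fundus_image(px, 256L,
                            meta = list(synthetic = TRUE, seed = p$seed)),
       od_truth = truth,
       vessel_mask = env$mask)
}
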