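#' Region-of-interest specification
#'
#' Geometry of the analysis crop: a square of side `od_multiple` optic-disc
#' diameters centred on the disc, resampled to `out_height x out_width`.
#' The defaults replicate the study protocol (4 disc diameters, 729 x 485
#' output); `square_out = TRUE` switches to a geometry-preserving 512 x 512
#' output instead.
#'
#' @param od_multiple ROI side length in optic-disc diameters.
#' @param out_height,out_width output raster size in pixels.
#' @param interpolation resampling method; only `"bilinear"` is implemented.
#' @param square_out if `TRUE`, override the output size with 512 x 512.
#' @param max_pad_fraction reject the crop when more than this fraction of
#'   the square falls outside the image and must be edge-replicated.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(od_multiple = 4, out_height = 485L, out_width = 729L,
                     interpolation = "bilinear", square_out = FALSE,
                     max_pad_fraction = 0.25) {
  rf_assert(od_multiple > 0, "rf_param_error", "od_multiple must be positive")
  if (square_out) { out_height <- 512L; out_width <- 512L }
  rf_assert(out_height >= 64 && out_width >= 64, "rf_param_error",
            "output dimensions must be at least 64 px")
  rf_assert(interpolation == "bilinear", "rf_param_error",
            "unsupported interpolation: %s", interpolation)
  structure(list(od_multiple = od_multiple,
                 out_height = as.integer(out_height),
                 out_width = as.integer(out_width),
                 interpolation = interpolation,
                 max_pad_fraction = max_pad_fraction),
            class = "roi_spec")
}

# bilinear resampling of a matrix to (out_h, out_w); output pixel centres are
# mapped into the input with the half-pixel (align-corners = FALSE) convention
# so constant images stay constant and edges are never extrapolated.
.resample_bilinear <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  ry <- pmin(pmax((seq_len(out_h) - 0.5) * h / out_h + 0.5, 1), h)
  rx <- pmin(pmax((seq_len(out_w) - 0.5) * w / out_w + 0.5, 1), w)
  y0 <- pmin(floor(ry), h - 1); x0 <- pmin(floor(rx), w - 1)
  fy <- ry - y0; fx <- rx - x0
  a <- m[y0, x0, drop = FALSE];     b <- m[y0 + 1, x0, drop = FALSE]
  cc <- m[y0, x0 + 1, drop = FALSE]; d <- m[y0 + 1, x0 + 1, drop = FALSE]
  wy <- matrix(fy, out_h, out_w); wx <- matrix(fx, out_h, out_w, byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * wy * (1 - wx) +
    cc * (1 - wy) * wx + d * wy * wx
}

#' Extract the optic-disc-centred region of interest
#'
#' Crops a square of side `od_multiple * diameter` centred on the detected
#' disc, replicating edge pixels where the square leaves the image (the
#' padded fraction is reported via a message and the `pad_fraction`
#' attribute), and resamples it to the configured output size.
#'
#' @param gray a [gray_image()] (typically the inverted green channel).
#' @param od an [optic_disc()] anchoring the crop.
#' @param spec a [roi_spec()].
#' @return A `gray_image` of size `out_height x out_width`, with attributes
#'   `pad_fraction` and `crop_side`.
#' @export
extract_roi <- function(gray, od, spec = roi_spec()) {
  stopifnot(inherits(gray, "gray_image"), inherits(od, "optic_disc"),
            inherits(spec, "roi_spec"))
  h <- nrow(gray$pixels); w <- ncol(gray$pixels)
  side <- max(2L, as.integer(round(spec$od_multiple * od$diameter)))
  rows <- as.integer(round(od$center[1] - side / 2)) + seq_len(side)
  cols <- as.integer(round(od$center[2] - side / 2)) + seq_len(side)
  in_r <- rows >= 1 & rows <= h
  in_c <- cols >= 1 & cols <= w
  if (!any(in_r) || !any(in_c))
    rf_stop("rf_geometry_error", "ROI square lies entirely outside the image")
  pad_fraction <- 1 - mean(in_r) * mean(in_c)
  if (pad_fraction > spec$max_pad_fraction)
    rf_stop("rf_geometry_error",
            "ROI padding fraction %.2f exceeds the allowed %.2f",
            pad_fraction, spec$max_pad_fraction)
  if (pad_fraction > 0)
    message(sprintf("extract_roi: %.1f%% of the ROI square was edge-padded",
                    100 * pad_fraction))
  crop <- gray$pixels[pmin(pmax(rows, 1L), h), pmin(pmax(cols, 1L), w)]
  out <- .resample_bilinear(crop, spec$out_height, spec$out_width)
  res <- gray_image(matrix(as.integer(round(out)), spec$out_height,
                           spec$out_width),
                    gray$gray_levels)
  attr(res, "pad_fraction") <- pad_fraction
  attr(res, "crop_side") <- side
  res
}
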