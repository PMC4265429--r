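#' Fundus image container
#'
#' Wraps a 3-channel RGB raster of integer intensities in `[0, gray_levels-1]`
#' together with its gray-level count and free-form capture metadata.
#' Pixel layout is `[row, col, channel]` with channels R, G, B.
#'
#' @param pixels numeric array `height x width x 3` of integer intensities.
#' @param gray_levels number of representable intensities (256 for 8-bit).
#' @param meta optional named list of capture metadata.
#' @return An object of class `fundus_image`.
#' @seealso [load_fundus()], [extract_green_inverted()]
#' @export
fundus_image <- function(pixels, gray_levels = 256L, meta = list()) {
  rf_assert(is.array(pixels) && length(dim(pixels)) == 3 && dim(pixels)[3] == 3,
            "rf_input_error", "pixels must be a height x width x 3 array")
  d <- dim(pixels)
  rf_assert(d[1] >= 64 && d[2] >= 64, "rf_input_error",
            "image must be at least 64 x 64 (got %d x %d)", d[1], d[2])
  storage.mode(pixels) <- "integer"
  rf_assert(!anyNA(pixels), "rf_input_error", "image contains missing values")
  rf_assert(min(pixels) >= 0 && max(pixels) <= gray_levels - 1,
            "rf_input_error", "intensities must lie in [0, %d]", gray_levels - 1)
  structure(list(pixels = pixels, gray_levels = as.integer(gray_levels),
                 meta = meta),
            class = "fundus_image")
}

#' Single-channel intensity image
#'
#' The intensity surface consumed by the fractal estimator: a matrix of
#' integer gray levels in `[0, gray_levels-1]`, indexed `[row, col]`.
#'
#' @param pixels integer matrix of intensities.
#' @param gray_levels number of representable intensities.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, gray_levels = 256L) {
  rf_assert(is.matrix(pixels), "rf_input_error", "pixels must be a matrix")
  storage.mode(pixels) <- "integer"
  rf_assert(!anyNA(pixels), "rf_input_error", "image contains missing values")
  rf_assert(min(pixels) >= 0 && max(pixels) <= gray_levels - 1,
            "rf_input_error", "intensities must lie in [0, %d]", gray_levels - 1)
  structure(list(pixels = pixels, gray_levels = as.integer(gray_levels)),
            class = "gray_image")
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fundus_image> %d x %d px, RGB, %d gray levels\n",
              d[1], d[2], x$gray_levels))
  invisible(x)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, %d gray levels, range [%d, %d]\n",
              nrow(x$pixels), ncol(x$pixels), x$gray_levels,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read a fundus photograph from disk
#'
#' Decodes a PNG, TIFF or JPEG raster into a [fundus_image()].  Grayscale
#' files are promoted to three identical channels with a warning.  Intensities
#' are quantised to 8-bit (`gray_levels = 256`).
#'
#' @param path path to a PNG/TIFF/JPEG file.
#' @return A `fundus_image`.
#' @export
load_fundus <- function(path) {
  rf_assert(is.character(path) && length(path) == 1 && file.exists(path),
            "rf_input_error", "file not found: %s", paste(path, collapse = ","))
  ext <- tolower(tools::file_ext(path))
  dat <- tryCatch({
    if (ext == "png") {
      png::readPNG(path)
    } else if (ext %in% c("tif", "tiff") &&
               requireNamespace("tiff", quietly = TRUE)) {
      tiff::readTIFF(path)
    } else {
      # EBImage handles JPEG (and anything else its readers accept);
      # it stores [x, y(, c)], so transpose back to [row, col(, c)].
      im <- EBImage::imageData(suppressWarnings(EBImage::readImage(path)))
      if (length(dim(im)) == 2) t(im) else aperm(im, c(2, 1, 3))
    }
  }, error = function(e) {
    rf_stop("rf_input_error", "cannot decode image %s: %s",
            path, conditionMessage(e))
  })
  rf_assert(length(dat) > 0 && all(dim(dat)[1:2] > 0), "rf_input_error",
            "zero-area image: %s", path)
  if (length(dim(dat)) == 2) {
    warning(sprintf("grayscale image %s promoted to 3 identical channels",
                    basename(path)))
    dat <- array(rep(dat, 3), c(dim(dat), 3))
  } else if (dim(dat)[3] > 3) {
    dat <- dat[, , 1:3, drop = FALSE]  # drop alpha
  } else if (dim(dat)[3] == 2) {       # gray + alpha
    warning(sprintf("grayscale image %s promoted to 3 identical channels",
                    basename(path)))
    dat <- array(rep(dat[, , 1], 3), c(dim(dat)[1:2], 3))
  }
  px <- array(as.integer(round(dat * 255)), dim(dat))
  fundus_image(px, gray_levels = 256L, meta = list(path = path))
}

#' Write a gray image as an 8-bit PNG
#'
#' @param img a [gray_image()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  stopifnot(inherits(img, "gray_image"))
  png::writePNG(img$pixels / (img$gray_levels - 1), path)
  invisible(path)
}

#' Write a fundus image as an 8-bit PNG
#'
#' @param img a [fundus_image()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fundus_png <- function(img, path) {
  stopifnot(inherits(img, "fundus_image"))
  png::writePNG(img$pixels / (img$gray_levels - 1), path)
  invisible(path)
}

#' Inverted green channel
#'
#' Extracts the green channel and inverts it (`G-1 - g`), the representation
#' in which retinal vessels show the strongest contrast against the fundus
#' background.  Applying the inversion twice restores the green channel.
#'
#' @param img a [fundus_image()] (or a `gray_image`, which is inverted as-is).
#' @return A `gray_image` of the same dimensions.
#' @export
extract_green_inverted <- function(img) {
  if (inherits(img, "fundus_image")) {
    g <- img$pixels[, , 2]
  } else if (inherits(img, "gray_image")) {
    g <- img$pixels
  } else {
    rf_stop("rf_input_error", "expected a fundus_image or gray_image")
  }
  gray_image((img$gray_levels - 1L) - g, img$gray_levels)
}
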