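# Differential (grayscale) box counting after Sarkar & Chaudhuri, plus the
# classic binary box-counting comparator.  The image is viewed as a surface
# z = intensity over the (x, y) grid; at grid side s the intensity axis is
# divided into boxes of height s' = s * G / M (M = shorter image side), and
# each grid cell contributes the number of boxes spanned between its minimum
# and maximum gray level.

# reduce consecutive groups of `s` rows with binary function f (pmin/pmax);
# the last, possibly partial, group uses its actual extent
.row_group_reduce <- function(m, s, f) {
  h <- nrow(m)
  nf <- h %/% s
  out <- NULL
  if (nf > 0) {
    acc <- m[seq(1, by = s, length.out = nf), , drop = FALSE]
    if (s > 1) for (k in 2:s)
      acc <- f(acc, m[seq(k, by = s, length.out = nf), , drop = FALSE])
    out <- acc
  }
  if (h %% s > 0) {
    rows <- (nf * s + 1):h
    last <- m[rows[1], , drop = FALSE]
    for (k in rows[-1]) last <- f(last, m[k, , drop = FALSE])
    out <- rbind(out, last)
  }
  out
}

.block_min_max <- function(m, s) {
  list(min = t(.row_group_reduce(t(.row_group_reduce(m, s, pmin)), s, pmin)),
       max = t(.row_group_reduce(t(.row_group_reduce(m, s, pmax)), s, pmax)))
}

#' Boxes spanned by one grid cell
#'
#' Number of intensity boxes of height `box_height` intersected by a surface
#' patch whose gray levels span `[g_min, g_max]`: the difference-based count
#' `floor((g_max - g_min) / box_height) + 1`.  A flat cell occupies exactly
#' one box.  Vectorised over its arguments.
#'
#' @param g_min,g_max minimum and maximum gray level in the cell.
#' @param box_height box height in gray-level units (`s * G / M`).
#' @param variant `"difference"` (default) counts boxes spanned by the
#'   min-max difference and is exactly invariant to constant intensity
#'   offsets; `"absolute"` counts boxes between the absolute box indices of
#'   the two levels (`floor(g_max/h) - floor(g_min/h) + 1`), the
#'   fixed-partition reading used by some implementations.
#' @return Integer count(s), at least 1.
#' @export
dbc_cell_count <- function(g_min, g_max, box_height,
                           variant = c("difference", "absolute")) {
  variant <- match.arg(variant)
  rf_assert(all(box_height > 0), "rf_param_error", "box_height must be positive")
  if (any(g_min > g_max))
    rf_stop("rf_logic_error", "g_min exceeds g_max")
  if (variant == "difference")
    as.integer(floor((g_max - g_min) / box_height)) + 1L
  else
    as.integer(floor(g_max / box_height) - floor(g_min / box_height)) + 1L
}

#' Grid scales for dyadic box counting
#'
#' @param M analysis side length (shorter image side), pixels.
#' @param G gray-level count.
#' @param min_s,max_s smallest/largest grid side; scales are the powers of
#'   two in `[min_s, max_s]`.
#' @param include_s1 also include the degenerate single-pixel scale `s = 1`.
#' @return Data frame with columns `s`, `r` (= s/M) and `box_height`.
#' @export
grid_scales <- function(M, G = 256L, min_s = 2L, max_s = NULL,
                        include_s1 = FALSE) {
  if (is.null(max_s)) max_s <- M / 2
  rf_assert(max_s <= M / 2, "rf_config_error",
            "max_s must not exceed half the analysis side")
  lo <- max(1, floor(log2(min_s))); hi <- floor(log2(max_s))
  s <- if (hi < lo) numeric(0) else 2^(lo:hi)
  if (include_s1) s <- c(1L, s)
  data.frame(s = s, r = s / M, box_height = s * G / M)
}

#' Per-scale differential box count
#'
#' Sums [dbc_cell_count()] over all grid cells of side `s` tiling the image
#' (partial boundary cells are included with their actual pixel extents).
#'
#' @param img a [gray_image()] or integer matrix.
#' @param s grid side length in pixels.
#' @param G gray levels (taken from the image when it is a `gray_image`).
#' @param variant see [dbc_cell_count()].
#' @return The box count `N_r` as a numeric scalar.
#' @export
dbc_grid_counts <- function(img, s, G = NULL, variant = "difference") {
  m <- if (inherits(img, "gray_image")) img$pixels else img
  if (is.null(G)) G <- if (inherits(img, "gray_image")) img$gray_levels else 256L
  rf_assert(length(m) > 0, "rf_input_error", "empty image")
  M <- min(dim(m))
  rf_assert(s >= 1 && s <= M / 2 || s == 1, "rf_config_error",
            "grid side s=%g outside [1, M/2]", s)
  bh <- s * G / M
  mm <- .block_min_max(m, s)
  sum(dbc_cell_count(mm$min, mm$max, bh, variant))
}

# least-squares line with R^2 (natural logs already applied by callers)
.ols_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  icpt <- my - slope * mx
  res <- y - icpt - slope * x
  sst <- sum((y - my)^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 1
  list(slope = slope, intercept = icpt, r_squared = r2)
}

.box_count_curve <- function(scales, counts, fit, kind) {
  structure(list(scales = scales, counts = counts,
                 fd = fit$slope, intercept = fit$intercept,
                 r_squared = fit$r_squared, n_scales = nrow(scales),
                 kind = kind),
            class = "box_count_curve")
}

#' Differential box-counting fractal dimension
#'
#' Computes per-scale box counts over dyadic grid sides `s` in
#' `[min_s, max_s]` (defaults 2 and half the shorter image side) and fits
#' ordinary least squares of `log(N_r)` on `log(1/r)` (natural logarithm,
#' `r = s / M`).  The slope is the grayscale fractal dimension, which for
#' any intensity surface lies between 2 (a plane) and 3.
#'
#' @param img a [gray_image()] or integer matrix.
#' @param min_s,max_s smallest/largest dyadic grid side used in the fit.
#' @param include_s1 include the single-pixel scale (every cell then counts
#'   exactly one box, which carries no intensity information and drags the
#'   slope toward 2; off by default).
#' @param variant cell-count variant, see [dbc_cell_count()].
#' @param G gray-level count override.
#' @return A `box_count_curve` with fields `scales`, `counts`, `fd`,
#'   `intercept`, `r_squared`, `n_scales`.
#' @export
dbc_fd <- function(img, min_s = 2L, max_s = NULL, include_s1 = FALSE,
                   variant = "difference", G = NULL) {
  m <- if (inherits(img, "gray_image")) img$pixels else img
  if (is.null(G)) G <- if (inherits(img, "gray_image")) img$gray_levels else 256L
  M <- min(dim(m))
  sc <- grid_scales(M, G, min_s, max_s, include_s1)
  if (nrow(sc) < 3)
    rf_stop("rf_config_error",
            "only %d usable scales in [%g, %g]; need at least 3",
            nrow(sc), min_s, if (is.null(max_s)) M / 2 else max_s)
  counts <- vapply(sc$s, function(s) dbc_grid_counts(m, s, G, variant),
                   numeric(1))
  fit <- .ols_line(log(1 / sc$r), log(counts))
  .box_count_curve(sc, counts, fit, "dbc")
}

#' Binary box-counting fractal dimension
#'
#' Counts, at each dyadic grid side `s`, the grid cells containing at least
#' one foreground pixel, and fits `log N(s)` against `log(1/r)`.  The slope
#' lies in `[0, 2]`: 0 for a point, 1 for a line, 2 for a filled region.
#'
#' @param mask logical (or 0/1) matrix; must contain foreground.
#' @param min_s,max_s dyadic scale range as in [dbc_fd()].
#' @return A `box_count_curve` with `kind = "binary"`.
#' @export
binary_bc_fd <- function(mask, min_s = 2L, max_s = NULL) {
  m <- (mask > 0) * 1L
  rf_assert(sum(m) > 0, "rf_input_error", "mask has no foreground pixels")
  M <- min(dim(m))
  sc <- grid_scales(M, 2L, min_s, max_s)
  if (nrow(sc) < 3)
    rf_stop("rf_config_error", "fewer than 3 usable scales")
  counts <- vapply(sc$s, function(s) {
    mm <- .block_min_max(m, s)
    sum(mm$max > 0)
  }, numeric(1))
  fit <- .ols_line(log(1 / sc$r), log(counts))
  .box_count_curve(sc, counts, fit, "binary")
}

#' Percentile threshold segmentation of the enhanced image
#'
#' Marks as foreground the pixels strictly above the given intensity
#' percentile; a crude vessel segmentation used only by the binary
#' box-counting comparator.
#'
#' @param enhanced a [gray_image()].
#' @param percentile threshold percentile in (0, 100).
#' @return Logical matrix of the image size.
#' @export
segment_vessels <- function(enhanced, percentile = 85) {
  stopifnot(inherits(enhanced, "gray_image"))
  rf_assert(percentile > 0 && percentile < 100, "rf_param_error",
            "percentile must be in (0, 100)")
  px <- enhanced$pixels
  if (min(px) == max(px))
    rf_stop("rf_segmentation_error",
            "constant image: no threshold separates foreground from background")
  thr <- stats::quantile(px, percentile / 100, names = FALSE)
  px > thr
}

#' @export
print.box_count_curve <- function(x, ...) {
  cat(sprintf("<box_count_curve> %s, %d scales, fd = %.4f (R^2 = %.4f)\n",
              x$kind, x$n_scales, x$fd, x$r_squared))
  invisible(x)
}

#' @export
plot.box_count_curve <- function(x, ...) {
  lx <- log(1 / x$scales$r); ly <- log(x$counts)
  graphics::plot(lx, ly, xlab = "log(1/r)", ylab = "log(N_r)",
                 main = sprintf("fd = %.4f", x$fd), ...)
  graphics::abline(x$intercept, x$fd, lty = 2)
  invisible(x)
}

#' Serialise a box-count curve
#'
#' Writes the per-scale counts and fit either as CSV (columns `s`, `r`,
#' `N_r`, with the fitted slope, intercept and R-squared in comment
#' footer lines) or as JSON.
#'
#' @param curve a `box_count_curve`.
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, format = c("csv", "json")) {
  stopifnot(inherits(curve, "box_count_curve"))
  format <- match.arg(format)
  if (format == "json") {
    writeLines(jsonlite::toJSON(list(
      s = curve$scales$s, r = curve$scales$r, N_r = curve$counts,
      fd = curve$fd, intercept = curve$intercept,
      r_squared = curve$r_squared), auto_unbox = TRUE, digits = NA), path)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("s,r,N_r", con)
    for (i in seq_len(nrow(curve$scales)))
      writeLines(sprintf("%d,%.10g,%.10g", curve$scales$s[i],
                         curve$scales$r[i], curve$counts[i]), con)
    writeLines(sprintf("# fd,%.10g", curve$fd), con)
    writeLines(sprintf("# intercept,%.10g", curve$intercept), con)
    writeLines(sprintf("# r_squared,%.10g", curve$r_squared), con)
  }
  invisible(path)
}
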