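#' Algebraic least-squares circle fit
#'
#' Fits a circle to a set of boundary points by minimising the algebraic
#' (Kasa) residual, which for well-spread points closely approximates the
#' geometric least-squares circle.  Exact circle samples are recovered with
#' zero residual.
#'
#' @param points numeric matrix with two columns `(row, col)`; at least three
#'   non-collinear points.
#' @return A list with `center` (numeric `(row, col)`), `diameter`, and
#'   `fit_rms`, the root-mean-square radial residual in pixels.
#' @export
fit_circle <- function(points) {
  points <- as.matrix(points)
  rf_assert(is.numeric(points) && ncol(points) == 2 && nrow(points) >= 3,
            "rf_geometry_error", "need at least 3 (row, col) points")
  y <- points[, 1]; x <- points[, 2]
  # centre coordinates so the normal equations are well conditioned
  my <- mean(y); mx <- mean(x)
  u <- y - my; v <- x - mx
  A <- cbind(2 * u, 2 * v, 1)
  b <- u^2 + v^2
  qrA <- qr(A)
  if (qrA$rank < 3)
    rf_stop("rf_geometry_error", "points are collinear or degenerate")
  sol <- qr.coef(qrA, b)
  cy <- sol[1]; cx <- sol[2]
  r2 <- sol[3] + cy^2 + cx^2
  if (!is.finite(r2) || r2 <= 0)
    rf_stop("rf_geometry_error", "circle fit failed (non-positive radius)")
  r <- sqrt(r2)
  d <- sqrt((u - cy)^2 + (v - cx)^2)
  list(center = c(row = unname(cy + my), col = unname(cx + mx)),
       diameter = 2 * r,
       fit_rms = sqrt(mean((d - r)^2)))
}

#' Optic disc description
#'
#' @param center numeric `(row, col)` of the fitted disc centre, in pixels.
#' @param diameter fitted disc diameter in pixels.
#' @param boundary ordered matrix of boundary points `(row, col)`.
#' @param fit_rms RMS circle-fit residual in pixels.
#' @param method detection method used (`"snake"` or `"hough"`).
#' @return An object of class `optic_disc`.
#' @export
optic_disc <- function(center, diameter, boundary, fit_rms, method = "snake") {
  rf_assert(diameter > 0, "rf_geometry_error", "diameter must be positive")
  rf_assert(fit_rms >= 0, "rf_geometry_error", "fit_rms must be non-negative")
  structure(list(center = center, diameter = diameter, boundary = boundary,
                 fit_rms = fit_rms, method = method),
            class = "optic_disc")
}

#' @export
print.optic_disc <- function(x, ...) {
  cat(sprintf(
    "<optic_disc> centre (%.1f, %.1f), diameter %.1f px, rms %.2f px [%s]\n",
    x$center[1], x$center[2], x$diameter, x$fit_rms, x$method))
  invisible(x)
}

#' Serialise an optic disc to JSON
#'
#' @param od an [optic_disc()].
#' @param path optional file to write; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
od_to_json <- function(od, path = NULL) {
  stopifnot(inherits(od, "optic_disc"))
  js <- jsonlite::toJSON(list(center = unname(od$center),
                              diameter = od$diameter,
                              fit_rms = od$fit_rms,
                              method = od$method),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
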