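#' Define a tissue region with an optional region of interest
#'
#' A region is the rectangular extent of a (virtual) slide in micrometres
#' together with a region-of-interest (ROI) polygon inside it. The ROI is
#' the tumor area retained for analysis after discarding surrounding
#' normal tissue; it defaults to the full rectangle.
#'
#' @param width,height Extent of the slide in um; both must be positive.
#' @param roi Optional n x 2 matrix of ROI polygon vertices (um), open
#'   (first vertex not repeated). Must have positive area and lie within
#'   the rectangle.
#' @return An object of class `"region"` with elements `width`, `height`
#'   and `roi` (always a polygon matrix).
#' @examples
#' reg <- region(1000, 1000)
#' roi_area(reg)  # 1e6 um^2 = 1 mm^2
#' @export
region <- function(width, height, roi = NULL) {
  stopifnot(is.numeric(width), is.numeric(height), length(width) == 1L,
            length(height) == 1L)
  if (!is.finite(width) || !is.finite(height) || width <= 0 || height <= 0)
    stop("region width and height must be positive and finite")
  if (is.null(roi)) {
    roi <- rect_polygon(width, height)
  } else {
    roi <- as.matrix(roi)
    if (ncol(roi) != 2L || nrow(roi) < 3L)
      stop("roi must be an n x 2 matrix with at least 3 vertices")
    if (!all(is.finite(roi))) stop("roi vertices must be finite")
    # drop a repeated closing vertex if the caller supplied one
    n <- nrow(roi)
    if (all(roi[1, ] == roi[n, ])) roi <- roi[-n, , drop = FALSE]
    if (polygon_area(roi) <= 0) stop("roi polygon has zero area")
    tol <- 1e-9 * max(width, height)
    if (any(roi[, 1] < -tol | roi[, 1] > width + tol |
            roi[, 2] < -tol | roi[, 2] > height + tol))
      stop("roi polygon must lie inside the region rectangle")
  }
  structure(list(width = width, height = height, roi = roi),
            class = "region")
}

#' ROI area of a region
#'
#' @param reg A [region()] object.
#' @param units `"um2"` or `"mm2"`.
#' @return Area of the ROI polygon.
#' @export
roi_area <- function(reg, units = c("um2", "mm2")) {
  stopifnot(inherits(reg, "region"))
  units <- match.arg(units)
  a <- polygon_area(reg$roi)
  if (units == "mm2") a / 1e6 else a
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("region: %.6g x %.6g um, ROI area %.6g mm^2 (%d vertices)\n",
              x$width, x$height, roi_area(x, "mm2"), nrow(x$roi)))
  invisible(x)
}
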