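# Region-of-interest masks for slides and point patterns.
#
# An ROI mask is either a polygon in um (resolution-free) or a binary
# raster at a stated resolution. Both forms convert to a logical pixel
# mask at any target resolution; polygons are the primary form.

#' Create an ROI mask
#'
#' @param polygon n x 2 matrix of vertices in um (open polygon), or
#'   `NULL` when a raster is given.
#' @param raster Logical matrix (TRUE = inside ROI), or `NULL`.
#' @param resolution um/px of `raster` (required with a raster).
#' @return Object of class `"roi_mask"`.
#' @export
roi_mask <- function(polygon = NULL, raster = NULL, resolution = NULL) {
  if (is.null(polygon) == is.null(raster))
    stop("supply exactly one of polygon or raster")
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    stopifnot(ncol(polygon) == 2L, nrow(polygon) >= 3L)
    if (polygon_area(polygon) <= 0) stop("ROI polygon has zero area")
    structure(list(type = "polygon", polygon = polygon), class = "roi_mask")
  } else {
    raster <- as.matrix(raster) > 0
    if (!any(raster)) stop("ROI raster has empty foreground")
    if (is.null(resolution) || resolution <= 0)
      stop("raster ROI needs a positive resolution (um/px)")
    structure(list(type = "raster", raster = raster,
                   resolution = resolution), class = "roi_mask")
  }
}

#' Read an ROI mask from disk
#'
#' Binary PNG (foreground = bright pixels) or a CSV of polygon vertices
#' with columns `x_um`, `y_um`.
#'
#' @param path `.png` or `.csv` file.
#' @param resolution um/px, required for PNG masks.
#' @return An [roi_mask()].
#' @export
read_roi <- function(path, resolution = NULL) {
  if (!file.exists(path)) stop("ROI file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3L) px <- px[, , 1]
    roi_mask(raster = px > 0.5, resolution = resolution)
  } else if (ext == "csv") {
    d <- utils::read.csv(path)
    roi_mask(polygon = cbind(d$x_um, d$y_um))
  } else stop("unsupported ROI format: .", ext)
}

#' @rdname read_roi
#' @param mask An [roi_mask()] (polygon form) to write as CSV.
#' @export
write_roi_csv <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"), mask$type == "polygon")
  utils::write.csv(data.frame(x_um = mask$polygon[, 1],
                              y_um = mask$polygon[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

# Logical pixel mask for an image of `dims` = c(rows, cols) at
# `resolution` um/px. Pixel centres at ((c-0.5)*res, (r-0.5)*res).
roi_rasterize <- function(mask, dims, resolution) {
  stopifnot(inherits(mask, "roi_mask"))
  nr <- dims[1]; nc <- dims[2]
  if (mask$type == "polygon") {
    cx <- (seq_len(nc) - 0.5) * resolution
    cy <- (seq_len(nr) - 0.5) * resolution
    pts <- cbind(rep(cx, each = nr), rep(cy, times = nc))
    matrix(points_in_polygon(pts[, 1], pts[, 2], mask$polygon), nr, nc)
  } else {
    # nearest-neighbour lookup into the stored raster
    src_r <- pmin(nrow(mask$raster),
                  pmax(1L, round((seq_len(nr) - 0.5) * resolution /
                                   mask$resolution + 0.5)))
    src_c <- pmin(ncol(mask$raster),
                  pmax(1L, round((seq_len(nc) - 0.5) * resolution /
                                   mask$resolution + 0.5)))
    mask$raster[src_r, src_c, drop = FALSE]
  }
}

# TRUE/FALSE for arbitrary points in um
roi_contains <- function(mask, x, y) {
  if (mask$type == "polygon") return(points_in_polygon(x, y, mask$polygon))
  r <- pmax(1L, pmin(nrow(mask$raster), ceiling(y / mask$resolution)))
  c <- pmax(1L, pmin(ncol(mask$raster), ceiling(x / mask$resolution)))
  mask$raster[cbind(r, c)]
}

#' Restrict a slide or point pattern to an ROI
#'
#' For a slide, pixels outside the ROI are set to `NA` (a sentinel every
#' downstream statistic excludes) and the pixel mask is attached as
#' attribute `"mask"`. For a point pattern, points outside the ROI are
#' dropped. An empty intersection is an error.
#'
#' @param x A [virtual_slide()] or [point_pattern()].
#' @param mask An [roi_mask()].
#' @return Object of the same class as `x`.
#' @export
apply_roi <- function(x, mask) {
  stopifnot(inherits(mask, "roi_mask"))
  if (inherits(x, "virtual_slide")) {
    m <- roi_rasterize(mask, slide_dim(x), x$resolution)
    if (!any(m)) stop("ROI does not intersect the slide")
    px <- x$pixels
    for (ch in 1:3) { v <- px[, , ch]; v[!m] <- NA_real_; px[, , ch] <- v }
    out <- virtual_slide(px, x$resolution)
    attr(out, "mask") <- m
    out
  } else if (inherits(x, "point_pattern")) {
    if (length(x$x)) {
      keep <- roi_contains(mask, x$x, x$y)
      x$x <- x$x[keep]; x$y <- x$y[keep]
    }
    x
  } else stop("apply_roi expects a virtual_slide or point_pattern")
}

# area of the ROI in mm^2, rasterized at `resolution` when needed
roi_mask_area_mm2 <- function(mask, dims = NULL, resolution = NULL) {
  if (mask$type == "polygon") return(polygon_area(mask$polygon) / 1e6)
  sum(mask$raster) * mask$resolution^2 / 1e6
}
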