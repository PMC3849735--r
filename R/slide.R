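# Virtual slides: RGB raster + physical resolution.
#
# Pixel convention: images are arrays [row, col, channel] with values in
# [0, 1]; row = y (downwards), col = x (rightwards); the centre of pixel
# (r, c) sits at ((c - 0.5) * res, (r - 0.5) * res) um. All coordinates
# above raw pixel access are micrometres.

#' Construct a virtual slide
#'
#' @param pixels Numeric array `[rows, cols, 3]` with values in `[0, 1]`
#'   (8-bit images are divided by 255 on read).
#' @param resolution Pixel size in um/px (> 0).
#' @return Object of class `"virtual_slide"`.
#' @export
virtual_slide <- function(pixels, resolution) {
  if (length(dim(pixels)) == 2L)
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (!is.finite(resolution) || resolution <= 0)
    stop("resolution must be positive (um/px)")
  structure(list(pixels = pixels, resolution = resolution),
            class = "virtual_slide")
}

#' @export
print.virtual_slide <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("virtual_slide: %d x %d px at %.4g um/px (%.4g x %.4g um)\n",
              d[2], d[1], x$resolution,
              d[2] * x$resolution, d[1] * x$resolution))
  invisible(x)
}

#' Pixel dimensions of a slide
#'
#' @param slide A [virtual_slide()].
#' @return Integer vector `c(rows, cols)`.
#' @export
slide_dim <- function(slide) dim(slide$pixels)[1:2]

# default colors: pale eosin-like background, dark DAB-brown nuclei
.bg_rgb  <- c(0.93, 0.89, 0.85)
.dab_rgb <- c(0.34, 0.20, 0.08)

#' Render a point pattern as a synthetic immunostained slide
#'
#' Draws each nucleus as a dark-brown (DAB-like) disc on a pale
#' background, then adds i.i.d. Gaussian pixel noise. A synthetic
#' stand-in for a PHH3-stained slide: detection downstream is
#' intensity-based, so flat discs suffice and no chromatin texture is
#' simulated.
#'
#' @param pattern A [point_pattern()].
#' @param resolution Output pixel size, um/px.
#' @param nucleus_radius Disc radius in um; must be at least one pixel
#'   (`>= resolution`).
#' @param stain_contrast Stain strength in `[0, 1]`: 0 leaves the
#'   background, 1 paints the full DAB color.
#' @param noise_sd Gaussian noise standard deviation in 8-bit gray
#'   levels (applied per channel, values clipped to `[0, 1]`).
#' @param seed Integer seed for the noise.
#' @return A [virtual_slide()] with dimensions
#'   `ceiling(region extent / resolution)`.
#' @export
render_slide <- function(pattern, resolution, nucleus_radius,
                         stain_contrast = 0.9, noise_sd = 2, seed = 1L) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (!is.finite(resolution) || resolution <= 0)
    stop("resolution must be positive")
  if (nucleus_radius < resolution)
    stop("nucleus_radius below one pixel: increase radius or resolution")
  stopifnot(stain_contrast >= 0, stain_contrast <= 1, noise_sd >= 0)
  reg <- pattern$region
  nr <- as.integer(ceiling(reg$height / resolution))
  nc <- as.integer(ceiling(reg$width / resolution))
  img <- array(rep(.bg_rgb, each = nr * nc), dim = c(nr, nc, 3L))
  stain <- matrix(0, nr, nc)   # per-pixel stain fraction
  rad_px <- nucleus_radius / resolution
  for (k in seq_along(pattern$x)) {
    cc <- pattern$x[k] / resolution + 0.5  # pixel-centre coordinates
    rr <- pattern$y[k] / resolution + 0.5
    c0 <- max(1L, floor(cc - rad_px)); c1 <- min(nc, ceiling(cc + rad_px))
    r0 <- max(1L, floor(rr - rad_px)); r1 <- min(nr, ceiling(rr + rad_px))
    if (c0 > c1 || r0 > r1) next
    rows <- r0:r1; cols <- c0:c1
    d2 <- outer((rows - rr)^2, (cols - cc)^2, `+`)
    stain[rows, cols] <- pmax(stain[rows, cols], (d2 <= rad_px^2) * 1)
  }
  mix <- stain * stain_contrast
  for (ch in 1:3)
    img[, , ch] <- img[, , ch] * (1 - mix) + .dab_rgb[ch] * mix
  if (noise_sd > 0) {
    old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
    img <- img + stats::rnorm(length(img), 0, noise_sd / 255)
    img[img < 0] <- 0; img[img > 1] <- 1
  }
  virtual_slide(img, resolution)
}

#' Read a slide image (PNG or TIFF)
#'
#' Plain PNG/TIFF rasters are read directly; for tiled/pyramidal TIFF
#' files the first (highest-resolution) directory is used. Gray images
#' are expanded to RGB; an alpha channel, if present, is dropped.
#'
#' @param path Image file; format chosen by extension
#'   (`.png`, `.tif`/`.tiff`).
#' @param resolution Pixel size of the stored image, um/px.
#' @return A [virtual_slide()].
#' @export
read_slide <- function(path, resolution) {
  if (!file.exists(path)) stop("slide file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      r <- tiff::readTIFF(path, all = TRUE)
      if (is.list(r)) r[[1]] else r
    },
    stop("unsupported slide format: .", ext))
  if (length(dim(px)) == 3L && dim(px)[3] >= 3L)
    px <- px[, , 1:3, drop = FALSE]
  virtual_slide(px, resolution)
}

#' Write a slide to PNG or TIFF
#'
#' @param slide A [virtual_slide()].
#' @param path Output path; format chosen by extension.
#' @export
write_slide <- function(slide, path) {
  stopifnot(inherits(slide, "virtual_slide"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(slide$pixels, path),
    tif = ,
    tiff = tiff::writeTIFF(slide$pixels, path),
    stop("unsupported slide format: .", ext))
  invisible(path)
}
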