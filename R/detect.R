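# Detection of immunopositive (mitotic) nuclei on a stained slide.
#
# Chain: color deconvolution into a DAB-like stain optical density,
# threshold (Otsu on the OD histogram unless given), connected
# components, size filter. Returns centroids in um, areas in um^2 and
# mean stain OD per nucleus.

# Ruifrok-Johnston style normalized stain OD vectors (rows):
# hematoxylin, eosin, DAB. Overridable via the `stains` argument.
.default_stains <- local({
  m <- rbind(h   = c(0.650, 0.704, 0.286),
             e   = c(0.072, 0.990, 0.105),
             dab = c(0.268, 0.570, 0.776))
  m / sqrt(rowSums(m^2))
})

# per-pixel stain concentration maps from an RGB [0,1] array
stain_deconvolve <- function(pixels, stains = .default_stains) {
  od <- -log10(pmax(pixels, 1 / 255))      # optical density per channel
  nr <- dim(od)[1]; nc <- dim(od)[2]
  flat <- matrix(od, nr * nc, 3L)
  conc <- flat %*% solve(t(stains))        # unmix: OD = conc %*% stains
  list(h   = matrix(conc[, 1], nr, nc),
       e   = matrix(conc[, 2], nr, nc),
       dab = matrix(conc[, 3], nr, nc))
}

otsu_threshold <- function(vals) {
  vals <- vals[is.finite(vals)]
  rng <- range(vals)
  if (diff(rng) <= 0) return(rng[1])
  img <- EBImage::Image(matrix((vals - rng[1]) / diff(rng), nrow = 1L))
  rng[1] + EBImage::otsu(img, range = c(0, 1)) * diff(rng)
}

#' Detect positively stained nuclei
#'
#' Computes a brown-stain (DAB) optical density by color deconvolution
#' with fixed stain vectors, thresholds it, labels connected components
#' (8-connectivity: touching discs merge into one detection) and filters
#' them by area. Intended for high-resolution input (<= 1 um/px); no
#' pixels above threshold yields an empty set, not an error.
#'
#' @param slide A [virtual_slide()]; if produced by [apply_roi()] its
#'   pixel mask is honoured.
#' @param mask Optional [roi_mask()] applied before detection.
#' @param min_area,max_area Component area limits in um^2.
#' @param stain_threshold Optical-density threshold on the DAB channel;
#'   `NULL` selects it by Otsu's method on the ROI histogram.
#' @param stains 3 x 3 matrix of stain OD vectors (rows h, e, dab).
#' @return A `data.frame` of class `"nucleus_set"` with columns `x_um`,
#'   `y_um`, `area_um2`, `mean_od`; attributes `resolution` and
#'   `threshold`.
#' @export
detect_positive_nuclei <- function(slide, mask = NULL,
                                   min_area = 4, max_area = 1000,
                                   stain_threshold = NULL,
                                   stains = .default_stains) {
  stopifnot(inherits(slide, "virtual_slide"))
  if (!is.null(mask)) slide <- apply_roi(slide, mask)
  pxmask <- attr(slide, "mask")
  res <- slide$resolution
  px <- slide$pixels
  valid <- is.finite(px[, , 1])
  if (!is.null(pxmask)) valid <- valid & pxmask
  px[is.na(px)] <- 1  # sentinel -> background white; excluded via `valid`
  dab <- stain_deconvolve(px, stains)$dab
  if (is.null(stain_threshold))
    stain_threshold <- otsu_threshold(dab[valid])
  bin <- dab > stain_threshold & valid
  empty <- nucleus_set(numeric(0), numeric(0), numeric(0), numeric(0),
                       res, stain_threshold)
  if (!any(bin)) return(empty)
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  lab <- as.integer(EBImage::imageData(lab))
  keep <- lab > 0L
  if (!any(keep)) return(empty)
  nr <- nrow(bin)
  idx <- which(keep)
  lv <- lab[idx]
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  npix <- tabulate(lv)
  comp <- which(npix > 0)
  sum_r <- rowsum(as.numeric(rows), lv)[, 1]
  sum_c <- rowsum(as.numeric(cols), lv)[, 1]
  sum_od <- rowsum(as.numeric(dab[idx]), lv)[, 1]
  area <- npix[comp] * res^2
  ok <- area >= min_area & area <= max_area
  nucleus_set(x_um = (sum_c[ok] / npix[comp][ok] - 0.5) * res,
              y_um = (sum_r[ok] / npix[comp][ok] - 0.5) * res,
              area_um2 = area[ok],
              mean_od = sum_od[ok] / npix[comp][ok],
              resolution = res, threshold = stain_threshold)
}

nucleus_set <- function(x_um, y_um, area_um2, mean_od, resolution,
                        threshold = NA_real_) {
  d <- data.frame(x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                  area_um2 = as.numeric(area_um2),
                  mean_od = as.numeric(mean_od))
  rownames(d) <- NULL
  attr(d, "resolution") <- resolution
  attr(d, "threshold") <- threshold
  class(d) <- c("nucleus_set", "data.frame")
  d
}

#' Mitotic index per 1.7 mm^2
#'
#' The mitosis count normalized to the conventional 1.7 mm^2 reference
#' area (about ten high-power fields).
#'
#' @param nuclei A `nucleus_set` (or anything with `nrow()`), or a count.
#' @param roi_area_mm2 Analyzed ROI area in mm^2 (> 0).
#' @return Mitoses per 1.7 mm^2.
#' @examples
#' compute_mitotic_index(100, 17)  # 10
#' @export
compute_mitotic_index <- function(nuclei, roi_area_mm2) {
  if (!is.finite(roi_area_mm2) || roi_area_mm2 <= 0)
    stop("roi_area_mm2 must be positive")
  n <- if (is.numeric(nuclei) && length(nuclei) == 1L) nuclei else nrow(nuclei)
  n * 1.7 / roi_area_mm2
}

#' Convert detected nuclei to a point pattern
#'
#' @param nuclei A `nucleus_set`.
#' @param reg The [region()] the nuclei live in.
#' @return A [point_pattern()].
#' @export
as_point_pattern <- function(nuclei, reg) {
  keep <- points_in_polygon(nuclei$x_um, nuclei$y_um, reg$roi)
  point_pattern(nuclei$x_um[keep], nuclei$y_um[keep], reg)
}
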