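# Haralick gray-level co-occurrence features on the working-resolution
# image, where one pixel is roughly one cell. Energy measures textural
# uniformity; correlation measures how strongly neighbouring pixel
# levels co-vary.

#' Quantize an image to G gray levels inside the ROI
#'
#' Luminance (Rec. 709 weights) of ROI pixels is binned linearly from
#' the ROI minimum to maximum into `levels` equal-width bins. Pixels
#' outside the ROI (or `NA` after [apply_roi()]) are marked invalid and
#' never enter a co-occurrence pair. A constant image lands in a single
#' bin, which is valid.
#'
#' @param slide A [virtual_slide()], or a numeric matrix of intensities.
#' @param levels Number of gray levels G (>= 2).
#' @param mask Optional [roi_mask()].
#' @return Integer matrix with values in `1..G` and `NA` outside the
#'   ROI; attribute `levels`.
#' @export
quantize_image <- function(slide, levels = 16, mask = NULL) {
  if (levels < 2) stop("levels must be >= 2")
  if (inherits(slide, "virtual_slide")) {
    if (!is.null(mask)) slide <- apply_roi(slide, mask)
    px <- slide$pixels
    lum <- 0.2126 * px[, , 1] + 0.7152 * px[, , 2] + 0.0722 * px[, , 3]
    pxmask <- attr(slide, "mask")
    if (!is.null(pxmask)) lum[!pxmask] <- NA_real_
  } else {
    lum <- as.matrix(slide)
    if (!is.null(mask))
      lum[!roi_rasterize(mask, dim(lum), 1)] <- NA_real_
  }
  valid <- is.finite(lum)
  if (!any(valid)) stop("ROI is empty")
  rng <- range(lum[valid])
  q <- matrix(NA_integer_, nrow(lum), ncol(lum))
  if (diff(rng) <= 0) {
    q[valid] <- 1L
  } else {
    q[valid] <- pmin(levels,
                     floor((lum[valid] - rng[1]) / diff(rng) * levels) + 1L)
  }
  attr(q, "levels") <- as.integer(levels)
  q
}

#' Default GLCM offsets
#'
#' The common distance-1 displacements at 0, 45, 90 and 135 degrees, as
#' `(dx, dy)` with x = columns (rightwards) and y = rows (downwards).
#'
#' @return 4 x 2 integer matrix.
#' @export
glcm_offsets_default <- function() {
  cbind(dx = c(1L, 1L, 0L, -1L), dy = c(0L, 1L, 1L, 1L))
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurring quantized levels at each pixel displacement
#' (both pixels must be valid), optionally symmetrized (each pair also
#' counted in reverse), summed over offsets and normalized to
#' probabilities.
#'
#' @param quantized Integer matrix from [quantize_image()] (`NA` =
#'   invalid).
#' @param offsets Integer matrix with columns `dx`, `dy` (pixels);
#'   default: distance 1 in 4 directions.
#' @param symmetric Count each pair in both orders (default TRUE).
#' @return Object of class `"glcm"`: G x G probability matrix with
#'   attributes `levels`, `offsets`, `symmetric`, `n_pairs`.
#' @export
compute_glcm <- function(quantized, offsets = glcm_offsets_default(),
                         symmetric = TRUE) {
  G <- attr(quantized, "levels")
  if (is.null(G)) G <- max(quantized, na.rm = TRUE)
  offsets <- matrix(as.integer(offsets), ncol = 2L,
                    dimnames = list(NULL, c("dx", "dy")))
  nr <- nrow(quantized); nc <- ncol(quantized)
  counts <- matrix(0, G, G)
  total <- 0L
  for (o in seq_len(nrow(offsets))) {
    dx <- offsets[o, 1]; dy <- offsets[o, 2]
    r1 <- max(1L, 1L - dy):min(nr, nr - dy)
    c1 <- max(1L, 1L - dx):min(nc, nc - dx)
    if (!length(r1) || !length(c1)) next
    a <- quantized[r1, c1, drop = FALSE]
    b <- quantized[r1 + dy, c1 + dx, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    ai <- a[ok]; bi <- b[ok]
    tab <- table(factor(ai, levels = 1:G), factor(bi, levels = 1:G))
    counts <- counts + unclass(tab)
    total <- total + length(ai)
  }
  if (total == 0L) stop("no valid co-occurring pixel pairs")
  if (symmetric) counts <- counts + t(counts)
  dimnames(counts) <- NULL
  p <- counts / sum(counts)
  structure(p, class = "glcm", levels = G, offsets = offsets,
            symmetric = symmetric, n_pairs = total)
}

#' Haralick energy (angular second moment)
#'
#' `sum(p^2)` over the GLCM; 1 for a perfectly uniform texture
#' (single occupied entry), `1/G^2` at the opposite extreme of a
#' uniform GLCM.
#'
#' @param glcm A [compute_glcm()] result.
#' @return Energy in `(0, 1]`.
#' @export
haralick_energy <- function(glcm) {
  sum(unclass(glcm)^2)
}

#' Haralick correlation
#'
#' Correlation of the row and column level indices under the GLCM joint
#' distribution: `sum((i - mu_i) (j - mu_j) p(i, j)) / (sd_i * sd_j)`,
#' in `[-1, 1]`. When either marginal standard deviation is zero (a
#' constant image) the value is 0 by convention.
#'
#' @param glcm A [compute_glcm()] result.
#' @return Correlation in `[-1, 1]`.
#' @export
haralick_correlation <- function(glcm) {
  p <- unclass(glcm)
  G <- nrow(p)
  i <- seq_len(G)
  pi_ <- rowSums(p); pj_ <- colSums(p)
  mi <- sum(i * pi_); mj <- sum(i * pj_)
  si <- sqrt(sum((i - mi)^2 * pi_)); sj <- sqrt(sum((i - mj)^2 * pj_))
  if (si * sj <= .Machine$double.eps) return(0)
  cov <- sum(outer(i - mi, i - mj) * p)
  cov / (si * sj)
}

#' Extended Haralick features
#'
#' A few additional classical GLCM statistics (contrast, homogeneity,
#' entropy), provided for exploration; only energy and correlation are
#' part of the validated feature surface.
#'
#' @param glcm A [compute_glcm()] result.
#' @return Named numeric vector.
#' @export
haralick_extended <- function(glcm) {
  p <- unclass(glcm)
  G <- nrow(p)
  dif <- abs(outer(seq_len(G), seq_len(G), `-`))
  nz <- p > 0
  c(contrast = sum(dif^2 * p),
    homogeneity = sum(p / (1 + dif)),
    entropy = -sum(p[nz] * log(p[nz])))
}
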