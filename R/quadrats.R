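# Quadrat counts and dispersion indices.
#
# The tissue is cut into an axis-aligned grid of square quadrats over
# the ROI bounding box; per-quadrat nucleus counts support Fisher's
# index of dispersion (variance/mean, ~1 under complete spatial
# randomness, >1 under clustering) and the normalized variance of
# density. Quadrats are retained for statistics only when at least half
# of their area lies inside the ROI, and densities use the exact ROI
# overlap area, so boundary quadrats do not inflate the variance.

#' Quadrat counts of a point pattern
#'
#' @param pattern A [point_pattern()].
#' @param quadrat_side Quadrat side length in um (default 200, about
#'   50 px at the 4 um/px working resolution).
#' @param min_overlap Minimum ROI-overlap fraction for a quadrat to be
#'   retained in statistics (default 0.5).
#' @return Object of class `"quadrat_counts"`: data.frame with columns
#'   `ix`, `iy`, `count`, `overlap_um2`, `retained`; attributes
#'   `quadrat_side`, `origin`.
#' @export
quadrat_counts <- function(pattern, quadrat_side = 200, min_overlap = 0.5) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (!is.finite(quadrat_side) || quadrat_side <= 0)
    stop("quadrat_side must be positive")
  reg <- pattern$region
  roi <- reg$roi
  x0 <- min(roi[, 1]); y0 <- min(roi[, 2])
  nx <- max(1L, ceiling((max(roi[, 1]) - x0) / quadrat_side - 1e-9))
  ny <- max(1L, ceiling((max(roi[, 2]) - y0) / quadrat_side - 1e-9))
  grid <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  overlap <- numeric(nrow(grid))
  full_rect <- isTRUE(all.equal(polygon_area(roi),
                                (max(roi[, 1]) - x0) * (max(roi[, 2]) - y0))) &&
               nrow(roi) == 4L
  for (q in seq_len(nrow(grid))) {
    qx0 <- x0 + (grid$ix[q] - 1L) * quadrat_side; qx1 <- qx0 + quadrat_side
    qy0 <- y0 + (grid$iy[q] - 1L) * quadrat_side; qy1 <- qy0 + quadrat_side
    if (full_rect) {
      overlap[q] <- max(0, min(qx1, max(roi[, 1])) - qx0) *
                    max(0, min(qy1, max(roi[, 2])) - qy0)
    } else {
      clip <- clip_rect(roi, qx0, qx1, qy0, qy1)
      overlap[q] <- if (is.null(clip)) 0 else polygon_area(clip)
    }
  }
  # bin the points
  cnt <- integer(nrow(grid))
  if (npoints(pattern)) {
    ix <- pmin(nx, pmax(1L, floor((pattern$x - x0) / quadrat_side) + 1L))
    iy <- pmin(ny, pmax(1L, floor((pattern$y - y0) / quadrat_side) + 1L))
    tab <- table(factor((iy - 1L) * nx + ix, levels = seq_len(nx * ny)))
    cnt <- as.integer(tab)[(grid$iy - 1L) * nx + grid$ix]
  }
  retained <- overlap >= min_overlap * quadrat_side^2
  if (sum(retained) < 4L)
    stop("fewer than 4 quadrats retained; decrease quadrat_side")
  out <- data.frame(ix = grid$ix, iy = grid$iy, count = cnt,
                    overlap_um2 = overlap, retained = retained)
  attr(out, "quadrat_side") <- quadrat_side
  attr(out, "origin") <- c(x0, y0)
  class(out) <- c("quadrat_counts", "data.frame")
  out
}

#' Fisher's index of dispersion
#'
#' Variance-to-mean ratio of the retained quadrat counts (sample
#' variance, n-1 denominator). Approximately 1 under complete spatial
#' randomness, above 1 for clustered patterns, below 1 for regular ones.
#'
#' @param counts A [quadrat_counts()] object.
#' @return Dimensionless dispersion index.
#' @export
fisher_index <- function(counts) {
  stopifnot(inherits(counts, "quadrat_counts"))
  k <- counts$count[counts$retained]
  if (length(k) < 2L) stop("need at least 2 retained quadrats")
  m <- mean(k)
  if (m <= 0) stop("mean quadrat count is zero")
  stats::var(k) / m
}

#' Normalized variance of density
#'
#' Squared coefficient of variation of the per-quadrat density
#' (count / ROI-overlap area): sample variance of densities divided by
#' the squared mean density. Dimensionless and invariant to a global
#' rescaling of the intensity.
#'
#' @param counts A [quadrat_counts()] object.
#' @return Dimensionless normalized density variance.
#' @export
normalized_density_variance <- function(counts) {
  stopifnot(inherits(counts, "quadrat_counts"))
  sel <- counts$retained
  if (sum(sel) < 2L) stop("need at least 2 retained quadrats")
  dens <- counts$count[sel] / counts$overlap_um2[sel]
  m <- mean(dens)
  if (m <= 0) stop("mean density is zero")
  stats::var(dens) / m^2
}
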