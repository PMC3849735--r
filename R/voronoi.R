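# Voronoi pavements (zones of influence) of stained nuclei.
#
# Each nucleus gets the polygon of all locations closer to it than to
# any other nucleus, clipped to the ROI. Cells are built by successive
# half-plane clipping of the ROI polygon against perpendicular bisectors,
# visiting neighbours in order of increasing distance so clipping can
# stop once no remaining point can still cut the cell (a point at
# distance d only matters while d/2 is below the cell's current radius).
# Edge labels are tracked through the clipping so cell adjacency (shared
# bisector edge) comes out for free; adjacency drives hot-spot merging.

#' Voronoi tessellation of a point pattern clipped to the ROI
#'
#' @param pattern A [point_pattern()] with at least 3 non-collinear
#'   points.
#' @param reg Optional [region()]; defaults to `pattern$region`.
#' @return Object of class `"voronoi_tess"`: list with `cells` (list of
#'   vertex matrices), `areas` (um^2), `neighbors` (list of integer
#'   vectors, cells sharing an edge), `pattern`.
#' @export
voronoi_tessellation <- function(pattern, reg = NULL) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (is.null(reg)) reg <- pattern$region
  stopifnot(inherits(reg, "region"))
  n <- npoints(pattern)
  if (n < 3L) stop("need at least 3 points for a tessellation")
  x <- pattern$x; y <- pattern$y
  # collinearity check via the rank of centred coordinates
  cc <- cbind(x - mean(x), y - mean(y))
  if (min(svd(cc)$d) < 1e-9 * max(1, max(abs(cc))))
    stop("points are collinear; tessellation is degenerate")
  roi <- reg$roi
  cells <- vector("list", n)
  areas <- numeric(n)
  neighbors <- vector("list", n)
  for (i in seq_len(n)) {
    d2 <- (x - x[i])^2 + (y - y[i])^2
    ord <- order(d2)[-1]                     # neighbours, nearest first
    poly <- roi
    labels <- rep(NA_integer_, nrow(poly))
    rmax2 <- max((poly[, 1] - x[i])^2 + (poly[, 2] - y[i])^2)
    for (j in ord) {
      if (d2[j] > 4 * rmax2) break           # bisector cannot reach cell
      # half-plane closer to i than j: (pj-pi).(p - mid) <= 0
      a <- x[j] - x[i]; b <- y[j] - y[i]
      cst <- a * (x[i] + x[j]) / 2 + b * (y[i] + y[j]) / 2
      r <- clip_halfplane(poly, a, b, cst, labels, new_label = j)
      if (is.null(r)) { poly <- NULL; break }
      poly <- r$poly; labels <- r$labels
      rmax2 <- max((poly[, 1] - x[i])^2 + (poly[, 2] - y[i])^2)
    }
    if (is.null(poly)) {  # numerically degenerate (e.g. duplicated point)
      cells[[i]] <- matrix(numeric(0), 0, 2)
      areas[i] <- 0
      neighbors[[i]] <- integer(0)
    } else {
      cells[[i]] <- poly
      areas[i] <- polygon_area(poly)
      neighbors[[i]] <- sort(unique(labels[!is.na(labels)]))
    }
  }
  structure(list(cells = cells, areas = areas, neighbors = neighbors,
                 pattern = pattern, region = reg),
            class = "voronoi_tess")
}

#' @export
print.voronoi_tess <- function(x, ...) {
  cat(sprintf("voronoi_tess: %d cells, total area %.6g mm^2\n",
              length(x$cells), sum(x$areas) / 1e6))
  invisible(x)
}

#' Variance of Voronoi pavement areas
#'
#' Sample (n-1) variance of the clipped cell areas; with
#' `normalized = TRUE` it is divided by the squared mean area, giving a
#' dimensionless squared coefficient of variation. Large values flag
#' heterogeneous proliferation: clusters make many small pavements and a
#' few large ones.
#'
#' @param tess A [voronoi_tessellation()].
#' @param normalized Divide by squared mean area?
#' @return Variance in um^4, or dimensionless if normalized.
#' @export
voronoi_area_variance <- function(tess, normalized = FALSE) {
  stopifnot(inherits(tess, "voronoi_tess"))
  a <- tess$areas
  if (length(a) < 2L) stop("need at least 2 cells")
  v <- stats::var(a)
  if (normalized) v / mean(a)^2 else v
}

#' Detect hot spots of proliferation
#'
#' Cells whose area falls below the given percentile of all cell areas
#' are flagged; flagged cells sharing a Voronoi edge are merged, and
#' groups of at least `min_cluster` cells are reported as hot spots.
#' Small adjacent pavements mark locally dense mitotic activity.
#'
#' @param tess A [voronoi_tessellation()].
#' @param area_percentile Percentile (0-100) below which a cell is
#'   flagged; 0 flags nothing.
#' @param min_cluster Minimum number of adjacent flagged cells.
#' @return List of hot spots, each a list with `cells` (indices),
#'   `n_cells`, `area_um2` and `hull` (convex hull of member vertices).
#' @export
detect_hot_spots <- function(tess, area_percentile = 10, min_cluster = 5) {
  stopifnot(inherits(tess, "voronoi_tess"),
            area_percentile >= 0, area_percentile <= 100)
  if (area_percentile == 0) return(list())
  cut <- stats::quantile(tess$areas, area_percentile / 100, names = FALSE)
  flagged <- which(tess$areas < cut)
  if (!length(flagged)) return(list())
  # connected components of the adjacency graph restricted to flagged cells
  comp <- rep(NA_integer_, length(tess$areas))
  nextc <- 0L
  for (s in flagged) {
    if (!is.na(comp[s])) next
    nextc <- nextc + 1L
    queue <- s; comp[s] <- nextc
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- intersect(tess$neighbors[[v]], flagged)
      nb <- nb[is.na(comp[nb])]
      comp[nb] <- nextc
      queue <- c(queue, nb)
    }
  }
  out <- list()
  for (k in seq_len(nextc)) {
    cells <- which(comp == k)
    if (length(cells) < min_cluster) next
    verts <- do.call(rbind, tess$cells[cells])
    hull <- verts[grDevices::chull(verts), , drop = FALSE]
    out[[length(out) + 1L]] <- list(cells = cells,
                                    n_cells = length(cells),
                                    area_um2 = sum(tess$areas[cells]),
                                    hull = hull)
  }
  out
}
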