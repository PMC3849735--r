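# Planar polygon utilities used by the ROI and Voronoi machinery.
# Polygons are n x 2 numeric matrices of vertices in order (open: the
# closing edge last->first is implicit). Coordinates are micrometres.

#' Signed and absolute polygon area
#'
#' Shoelace formula. Vertices may wind either way; `polygon_area()` returns
#' the absolute area.
#'
#' @param poly n x 2 numeric matrix of vertices (um), open (no repeated
#'   closing vertex needed).
#' @return Area in um^2.
#' @export
polygon_area <- function(poly) {
  abs(polygon_area_signed(poly))
}

polygon_area_signed <- function(poly) {
  if (is.null(poly) || nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(poly))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Test whether points fall inside a polygon
#'
#' @param x,y point coordinates (um).
#' @param poly n x 2 vertex matrix.
#' @return Logical vector.
#' @export
points_in_polygon <- function(x, y, poly) {
  if (length(x) == 0L) return(logical(0))
  bnd <- rbind(poly, poly[1, , drop = FALSE])
  mgcv::in.out(bnd, cbind(as.numeric(x), as.numeric(y)))
}

# Clip `poly` against the half-plane a*x + b*y <= c (Sutherland-Hodgman).
# `labels[k]` identifies the edge starting at vertex k (used to track
# which neighbour contributed each Voronoi cell edge); new edges created
# on the clip line get `new_label`. Returns list(poly, labels) or NULL
# when the intersection is empty.
clip_halfplane <- function(poly, a, b, c, labels = NULL, new_label = NA_integer_) {
  n <- nrow(poly)
  if (is.null(labels)) labels <- rep(NA_integer_, n)
  d <- a * poly[, 1] + b * poly[, 2] - c
  inside <- d <= 1e-9 * max(1, abs(c))
  if (all(inside)) return(list(poly = poly, labels = labels))
  if (!any(inside)) return(NULL)
  nxt <- c(2:n, 1L)
  out_x <- numeric(2L * n); out_y <- numeric(2L * n)
  out_l <- integer(2L * n); m <- 0L
  for (i in seq_len(n)) {
    j <- nxt[i]
    if (inside[i]) {
      m <- m + 1L
      out_x[m] <- poly[i, 1]; out_y[m] <- poly[i, 2]; out_l[m] <- labels[i]
    }
    if (inside[i] != inside[j]) {
      t <- d[i] / (d[i] - d[j])
      m <- m + 1L
      out_x[m] <- poly[i, 1] + t * (poly[j, 1] - poly[i, 1])
      out_y[m] <- poly[i, 2] + t * (poly[j, 2] - poly[i, 2])
      # leaving: intersection starts the new clip edge; entering: the
      # intersection point continues the original edge i.
      out_l[m] <- if (inside[i]) new_label else labels[i]
    }
  }
  if (m < 3L) return(NULL)
  list(poly = cbind(out_x[seq_len(m)], out_y[seq_len(m)]),
       labels = out_l[seq_len(m)])
}

# Clip a polygon to an axis-aligned rectangle [x0,x1] x [y0,y1].
clip_rect <- function(poly, x0, x1, y0, y1) {
  r <- list(poly = poly, labels = rep(NA_integer_, nrow(poly)))
  for (hp in list(c(-1, 0, -x0), c(1, 0, x1), c(0, -1, -y0), c(0, 1, y1))) {
    r <- clip_halfplane(r$poly, hp[1], hp[2], hp[3], r$labels)
    if (is.null(r)) return(NULL)
  }
  r$poly
}

#' Rectangle polygon with origin at (0, 0)
#'
#' @param width,height Extent in um.
#' @return 4 x 2 vertex matrix.
#' @export
rect_polygon <- function(width, height) {
  cbind(c(0, width, width, 0), c(0, 0, height, height))
}
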