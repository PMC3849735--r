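# Synthetic spatial point patterns of mitotic nuclei.
#
# Intensities are expressed per mm^2 (the natural unit for mitotic
# densities); coordinates are micrometres. 1 mm^2 = 1e6 um^2.

UM2_PER_MM2 <- 1e6

#' Construct a point pattern
#'
#' Nucleus centroid locations inside the ROI of a [region()]. This is the
#' bridge between images (detected nuclei) and spatial statistics
#' (Voronoi pavements, quadrat counts).
#'
#' @param x,y Coordinates in um.
#' @param reg A [region()].
#' @param truth_label Optional generator label (`"csr"`, `"clustered"`,
#'   or `NA` for patterns of detected nuclei).
#' @param seed Optional seed recorded for provenance.
#' @return Object of class `"point_pattern"`: list with `x`, `y`,
#'   `region`, `truth_label`, `seed`.
#' @export
point_pattern <- function(x, y, reg, truth_label = NA_character_,
                          seed = NA_integer_) {
  stopifnot(inherits(reg, "region"), length(x) == length(y))
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) && !all(is.finite(x) & is.finite(y)))
    stop("point coordinates must be finite")
  if (length(x) && !all(points_in_polygon(x, y, reg$roi)))
    stop("all points must lie inside the region ROI")
  structure(list(x = x, y = y, region = reg,
                 truth_label = truth_label, seed = seed),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point_pattern: %d points (%s) in ROI of %.4g mm^2\n",
              length(x$x), x$truth_label, roi_area(x$region, "mm2")))
  invisible(x)
}

#' Number of points in a pattern
#'
#' @param p A [point_pattern()].
#' @return Integer count.
#' @export
npoints <- function(p) length(p$x)

#' Generate a completely spatially random (CSR) pattern
#'
#' Homogeneous Poisson process restricted to the ROI: the point count is
#' Poisson with mean `intensity * ROI area` and locations are uniform on
#' the ROI. CSR patterns are the homogeneity control: their quadrat
#' counts have a variance/mean ratio of 1 in expectation.
#'
#' @param intensity Points per mm^2 (>= 0).
#' @param reg A [region()].
#' @param seed Integer seed; identical seeds give identical patterns.
#' @return A [point_pattern()] with `truth_label = "csr"`.
#' @examples
#' p <- generate_csr_pattern(100, region(1000, 1000), seed = 1)
#' @export
generate_csr_pattern <- function(intensity, reg, seed) {
  stopifnot(inherits(reg, "region"))
  if (!is.finite(intensity) || intensity < 0)
    stop("intensity must be a non-negative number (points per mm^2)")
  lambda_um2 <- intensity / UM2_PER_MM2
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  # simulate on the bounding rectangle, thin to the ROI: the retained
  # process is Poisson(intensity * roi_area)
  n_rect <- stats::rpois(1L, lambda_um2 * reg$width * reg$height)
  x <- stats::runif(n_rect, 0, reg$width)
  y <- stats::runif(n_rect, 0, reg$height)
  keep <- points_in_polygon(x, y, reg$roi)
  point_pattern(x[keep], y[keep], reg, "csr", as.integer(seed))
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Specify a Thomas cluster process
#'
#' Stationary Poisson cluster process: parent centres form a Poisson
#' process, each parent begets a Poisson number of offspring scattered
#' isotropically with Gaussian standard deviation `offspring_sd`. The
#' expected intensity is `parent_intensity * offspring_mean`. Used as the
#' synthetic stand-in for heterogeneous proliferation ("hot spots").
#'
#' @param parent_intensity Parents per mm^2 (> 0).
#' @param offspring_mean Expected offspring per parent (> 0).
#' @param offspring_sd Gaussian scatter of offspring around the parent,
#'   in um (> 0).
#' @return Object of class `"cluster_spec"`.
#' @export
cluster_spec <- function(parent_intensity, offspring_mean, offspring_sd) {
  vals <- c(parent_intensity, offspring_mean, offspring_sd)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all cluster_spec fields must be strictly positive")
  structure(list(parent_intensity = parent_intensity,
                 offspring_mean = offspring_mean,
                 offspring_sd = offspring_sd),
            class = "cluster_spec")
}

#' Generate a Thomas-process clustered pattern
#'
#' Parents are simulated on the region rectangle expanded by a 4 sd
#' buffer (so clusters straddling the boundary contribute correctly);
#' offspring falling outside the ROI are discarded.
#'
#' @param spec A [cluster_spec()].
#' @param reg A [region()].
#' @param seed Integer seed.
#' @return A [point_pattern()] with `truth_label = "clustered"`.
#' @export
generate_clustered_pattern <- function(spec, reg, seed) {
  stopifnot(inherits(spec, "cluster_spec"), inherits(reg, "region"))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  buf <- 4 * spec$offspring_sd
  w <- reg$width + 2 * buf; h <- reg$height + 2 * buf
  n_par <- stats::rpois(1L, spec$parent_intensity / UM2_PER_MM2 * w * h)
  if (n_par == 0L)
    return(point_pattern(numeric(0), numeric(0), reg, "clustered",
                         as.integer(seed)))
  px <- stats::runif(n_par, -buf, reg$width + buf)
  py <- stats::runif(n_par, -buf, reg$height + buf)
  n_off <- stats::rpois(n_par, spec$offspring_mean)
  x <- rep(px, n_off) + stats::rnorm(sum(n_off), 0, spec$offspring_sd)
  y <- rep(py, n_off) + stats::rnorm(sum(n_off), 0, spec$offspring_sd)
  inside <- x >= 0 & x <= reg$width & y >= 0 & y <= reg$height
  x <- x[inside]; y <- y[inside]
  if (length(x)) {
    keep <- points_in_polygon(x, y, reg$roi)
    x <- x[keep]; y <- y[keep]
  }
  point_pattern(x, y, reg, "clustered", as.integer(seed))
}

#' Write / read a point pattern as CSV
#'
#' Columns `x_um`, `y_um`. Reading requires the region to be supplied.
#' @param pattern A [point_pattern()].
#' @param path File path.
#' @export
write_pattern_csv <- function(pattern, path) {
  stopifnot(inherits(pattern, "point_pattern"))
  utils::write.csv(data.frame(x_um = pattern$x, y_um = pattern$y),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pattern_csv
#' @param reg A [region()] the points belong to.
#' @export
read_pattern_csv <- function(path, reg) {
  d <- utils::read.csv(path)
  point_pattern(d$x_um, d$y_um, reg)
}
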