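test_that("Voronoi tessellation: conservation, symmetry, degeneracy", {
  reg <- mm_region()
  # 4 points at quadrant centres -> 4 equal cells of a quarter each
  p4 <- point_pattern(c(250, 750, 250, 750), c(250, 250, 750, 750), reg)
  t4 <- voronoi_tessellation(p4)
  expect_all_close(t4$areas, rep(250000, 4), tol = 1e-6)
  expect_lt(abs(sum(t4$areas) - roi_area(reg)) / roi_area(reg), 1e-3)

  expect_error(voronoi_tessellation(point_pattern(c(1, 2), c(1, 2), reg)),
               "at least 3")
  coll <- point_pattern(c(100, 500, 900), c(100, 500, 900), reg)
  expect_error(voronoi_tessellation(coll), "collinear")
})

test_that("every probe point lands in the cell of its nearest generator", {
  reg <- mm_region()
  p <- generate_csr_pattern(50, reg, 13)
  tess <- voronoi_tessellation(p)
  expect_lt(abs(sum(tess$areas) - roi_area(reg)) / roi_area(reg), 1e-3)
  set.seed(7)
  px <- runif(2000, 0, 1000); py <- runif(2000, 0, 1000)
  nearest <- apply((outer(px, p$x, "-")^2 + outer(py, p$y, "-")^2), 1,
                   which.min)
  ok <- vapply(seq_along(px), function(i)
    isTRUE(points_in_polygon(px[i], py[i], tess$cells[[nearest[i]]])),
    logical(1))
  # probes exactly on a cell edge may fall either way; none may land in
  # a wrong interior
  wrong <- which(!ok)
  for (i in wrong) {
    d <- sqrt((px[i] - p$x)^2 + (py[i] - p$y)^2)
    expect_lt(diff(sort(d)[1:2]), 1e-6 * 1000)
  }
  expect_lt(length(wrong) / length(px), 0.001)
})

test_that("tessellation is conserved on a non-convex ROI", {
  roi <- cbind(c(0, 1000, 1000, 600, 600, 0),
               c(0, 0, 400, 400, 1000, 1000))
  reg <- region(1000, 1000, roi)
  p <- generate_csr_pattern(120, reg, 3)
  tess <- voronoi_tessellation(p)
  expect_lt(abs(sum(tess$areas) - roi_area(reg)) / roi_area(reg), 1e-3)
})

test_that("Voronoi area variance: hand values and cluster sensitivity", {
  fake <- structure(list(areas = c(1e6, 2e6, 3e6)), class = "voronoi_tess")
  expect_equal(voronoi_area_variance(fake), 1e12)        # 1 mm^4
  expect_equal(voronoi_area_variance(fake, normalized = TRUE), 0.25)
  one <- structure(list(areas = 5), class = "voronoi_tess")
  expect_error(voronoi_area_variance(one), "at least 2")

  # interior cells of a regular lattice have (near) zero normalized
  # variance
  lat <- lattice_pattern(10)
  tess <- voronoi_tessellation(lat)
  interior <- which(lat$x > 100 & lat$x < 900 & lat$y > 100 & lat$y < 900)
  a <- tess$areas[interior]
  expect_lt(stats::var(a) / mean(a)^2, 1e-6)

  # clustering inflates the pavement-area variance vs paired CSR
  reg <- mm_region()
  wins <- vapply(1:40, function(s) {
    pc <- generate_clustered_pattern(cluster_spec(15, 8, 30), reg, s)
    pr <- generate_csr_pattern(120, reg, s + 1000)
    if (npoints(pc) < 5 || npoints(pr) < 5) return(NA)
    voronoi_area_variance(voronoi_tessellation(pc), TRUE) >
      voronoi_area_variance(voronoi_tessellation(pr), TRUE)
  }, logical(1))
  expect_gte(sum(wins, na.rm = TRUE), 38)  # >= 95%
})

test_that("hot spots: construction, null calibration, empty percentile", {
  reg <- mm_region()
  # a single tight cluster of 20 points among 200 CSR points
  bg <- generate_csr_pattern(200, reg, 5)
  set.seed(6)
  cl <- cbind(500 + rnorm(20, 0, 12), 500 + rnorm(20, 0, 12))
  p <- point_pattern(c(bg$x, cl[, 1]), c(bg$y, cl[, 2]), reg)
  tess <- voronoi_tessellation(p)
  hs <- detect_hot_spots(tess, area_percentile = 10, min_cluster = 5)
  expect_equal(length(hs), 1L)
  cluster_idx <- npoints(bg) + seq_len(20)
  expect_gte(length(intersect(hs[[1]]$cells, cluster_idx)), 15L)
  expect_equal(hs[[1]]$n_cells, length(hs[[1]]$cells))

  expect_equal(detect_hot_spots(tess, area_percentile = 0), list())

  # CSR null: false-positive hot spots are uncommon at moderate density
  # (the rate grows with point count as chance chains of small adjacent
  # cells become likely; ~8% at 100 points/mm^2 by Monte-Carlo)
  fp <- vapply(1:60, function(s) {
    t0 <- voronoi_tessellation(generate_csr_pattern(100, reg, s + 100))
    length(detect_hot_spots(t0, 10, 5)) > 0
  }, logical(1))
  expect_lte(mean(fp), 0.2)
})

test_that("quadrat counts: conservation, binning oracle, empty pattern", {
  reg <- mm_region()
  for (s in 1:20) {
    p <- generate_csr_pattern(150, reg, s)
    qc <- quadrat_counts(p, 200)
    expect_equal(sum(qc$count), npoints(p))  # exact tiling of the ROI
    # brute-force per-point binning oracle
    brute <- table(factor(paste(pmin(5, floor(p$x / 200) + 1),
                                pmin(5, floor(p$y / 200) + 1)),
                          levels = paste(rep(1:5, each = 5), rep(1:5, 5))))
    expect_equal(sort(as.integer(qc$count)), sort(as.integer(brute)))
  }
  empty <- point_pattern(numeric(0), numeric(0), reg)
  expect_true(all(quadrat_counts(empty, 200)$count == 0))
  expect_error(quadrat_counts(generate_csr_pattern(50, reg, 1), 2000),
               "quadrat")
})

test_that("boundary quadrats with under half ROI overlap are excluded", {
  roi <- cbind(c(0, 500, 500, 0), c(0, 0, 900, 900))
  reg <- region(1000, 1000, roi)
  p <- generate_csr_pattern(200, reg, 2)
  qc <- quadrat_counts(p, 200)
  # the top row of quadrats overlaps the 900-um-tall ROI by 50%: retained;
  # overlap areas must match the clipped geometry
  expect_true(all(qc$overlap_um2[qc$retained] >= 0.5 * 200^2))
  expect_equal(sum(qc$overlap_um2), polygon_area(roi))
})

test_that("Fisher index: hand values and degenerate errors", {
  fake <- function(k) {
    out <- data.frame(ix = seq_along(k), iy = 1L, count = k,
                      overlap_um2 = 200^2, retained = TRUE)
    attr(out, "quadrat_side") <- 200
    class(out) <- c("quadrat_counts", "data.frame")
    out
  }
  expect_equal(fisher_index(fake(c(4, 4, 4, 4))), 0)
  expect_equal(fisher_index(fake(c(1, 2, 3))), 0.5)  # var 1 / mean 2
  expect_error(fisher_index(fake(c(0, 0, 0))), "zero")
})

test_that("normalized density variance: hand value and scale freedom", {
  fake <- function(k, area = 1e6) {
    out <- data.frame(ix = seq_along(k), iy = 1L, count = k,
                      overlap_um2 = area, retained = TRUE)
    attr(out, "quadrat_side") <- sqrt(area)
    class(out) <- c("quadrat_counts", "data.frame")
    out
  }
  # densities 1 and 3 per mm^2: mean 2, sample variance 2 -> 0.5
  expect_equal(normalized_density_variance(fake(c(1, 3))), 0.5)
  expect_equal(normalized_density_variance(fake(c(5, 5, 5))), 0)
  # invariant under multiplying all counts by k
  k <- c(40, 55, 62, 38, 51)
  expect_lt(abs(normalized_density_variance(fake(4 * k)) -
                normalized_density_variance(fake(k))), 1e-12)
})

test_that("spatial features are invariant under rigid translation", {
  roi1 <- rbind(c(0, 0), c(700, 0), c(700, 700), c(0, 700))
  reg1 <- region(700, 700, roi1)
  p1 <- generate_csr_pattern(250, reg1, 23)
  reg2 <- region(1200, 1200, roi1 + 250)
  p2 <- point_pattern(p1$x + 250, p1$y + 250, reg2)
  expect_equal(fisher_index(quadrat_counts(p1, 175)),
               fisher_index(quadrat_counts(p2, 175)))
  expect_equal(voronoi_area_variance(voronoi_tessellation(p1), TRUE),
               voronoi_area_variance(voronoi_tessellation(p2), TRUE),
               tolerance = 1e-9)
})
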