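test_that("standardization: hand case, round trip, zero-SD error", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  s <- standardize_features(m)
  expect_equal(unname(s[, "a"]), c(-1, 0, 1))  # mean 2, sample SD 1
  expect_equal(colMeans(s), c(a = 0, b = 0))
  expect_equal(apply(s, 2, sd), c(a = 1, b = 1))

  # transform then inverse-transform is the identity
  back <- sweep(sweep(s, 2, attr(s, "scale"), "*"), 2,
                attr(s, "center"), "+")
  expect_all_close(back, m, tol = 1e-10)

  # already-standard column is unchanged
  z <- (1:7 - mean(1:7)) / sd(1:7)
  expect_all_close(standardize_features(cbind(z = z))[, 1], z, 1e-12)

  bad <- cbind(ok = c(1, 2, 3), flat = c(5, 5, 5))
  expect_error(standardize_features(bad), "flat")

  expect_all_close(apply_standardization(s, m), s, 1e-12)
})

test_that("redundancy pruning: duplicates, orthogonal, planted factors", {
  set.seed(2)
  x <- rnorm(100)
  dup <- cbind(f1 = x, f2 = x + rnorm(100, 0, 1e-6), f3 = rnorm(100))
  sel <- select_nonredundant(dup, 0.8)
  expect_length(intersect(sel, c("f1", "f2")), 1L)
  expect_true("f3" %in% sel)

  ortho <- qr.Q(qr(matrix(rnorm(400), 100, 4)))
  colnames(ortho) <- paste0("g", 1:4)
  expect_equal(select_nonredundant(ortho, 0.5), paste0("g", 1:4))

  # 9 features built from 4 latent factors + noisy duplicates reduce to
  # one representative per factor
  ft <- simulate_feature_table(400, seed = 9)
  groups <- c(quadrat_mean_density = 1, hot_spot_count = 1,
              haralick_entropy = 1, fisher_index = 3,
              voronoi_variance = 3, norm_density_variance = 3,
              haralick_correlation = 2, haralick_contrast = 2,
              haralick_energy = 4)
  sel <- select_nonredundant(as.matrix(ft$features[, -1]), 0.8)
  expect_length(sel, 4L)
  expect_equal(sort(unique(groups[sel])), 1:4)  # one per latent factor
})

test_that("PCA: exact 2D eigenstructure on constructed correlation", {
  # columns built with exact sample correlation r = 0.6:
  # eigenvalues 1 +/- r, loadings (1, 1)/sqrt(2) and (1, -1)/sqrt(2)
  set.seed(5)
  # exactly orthonormal, mean-zero columns
  Z <- qr.Q(qr(scale(matrix(rnorm(400), 200, 2), scale = FALSE)))
  z1 <- Z[, 1] / sd(Z[, 1]); z2 <- Z[, 2] / sd(Z[, 2])
  r <- 0.6
  m <- cbind(fisher_index = z1, voronoi_variance = r * z1 +
               sqrt(1 - r^2) * z2)
  model <- fit_pca(standardize_features(m), k = 2)
  expect_equal(model$explained_variance, c(1 + r, 1 - r), tolerance = 1e-8)
  expect_equal(model$explained_ratio[1], (1 + r) / 2, tolerance = 1e-8)
  expect_all_close(abs(model$loadings), matrix(1 / sqrt(2), 2, 2), 1e-8)
})

test_that("PCA invariants: orthonormality, ordering, completeness", {
  set.seed(11)
  m <- matrix(rnorm(600), 100, 6) %*% matrix(rnorm(36), 6, 6)
  colnames(m) <- paste0("f", 1:6)
  s <- standardize_features(m)
  model <- fit_pca(s, k = 6)
  expect_all_close(crossprod(model$loadings), diag(6), 1e-8)
  expect_true(all(diff(model$explained_variance) <= 1e-12))
  # full reconstruction reproduces the standardized matrix
  sc <- cp_scores(model, m)
  expect_all_close(sc %*% t(model$loadings), s, 1e-8)
  expect_error(fit_pca(s, k = 7), "exceeds")
})

test_that("eigen-based scores match prcomp up to component sign", {
  set.seed(19)
  m <- matrix(rnorm(500), 100, 5)
  m[, 2] <- m[, 1] * 0.7 + m[, 2]
  colnames(m) <- paste0("f", 1:5)
  s <- standardize_features(m)
  model <- fit_pca(s, k = 3)
  sc <- cp_scores(model, m)
  pr <- stats::prcomp(s, center = FALSE, scale. = FALSE)
  for (j in 1:3) {
    agree <- min(max(abs(sc[, j] - pr$x[, j])),
                 max(abs(sc[, j] + pr$x[, j])))
    expect_lt(agree, 1e-8)
  }
})

test_that("component orientation: flip, idempotence, variance unchanged", {
  set.seed(4)
  m <- cbind(fisher_index = rnorm(50), other = rnorm(50))
  model <- fit_pca(standardize_features(m), k = 2)
  expect_true(all(model$loadings["fisher_index", ] >= 0))
  twice <- orient_components(orient_components(model, "fisher_index"),
                             "fisher_index")
  expect_identical(twice$loadings, model$loadings)
  expect_identical(twice$explained_variance, model$explained_variance)
  expect_error(orient_components(model, "absent"), "not in the model")
})

test_that("scores from stored parameters equal joint fitting", {
  ft <- simulate_feature_table(200, seed = 31)
  fm <- as.matrix(ft$features[, -1])
  s <- standardize_features(fm)
  model <- fit_pca(s, k = 3)
  model$center <- attr(s, "center"); model$scale <- attr(s, "scale")
  sc_raw <- cp_scores(model, fm)         # standardizes internally
  model2 <- model; model2$center <- NULL; model2$scale <- NULL
  sc_std <- cp_scores(model2, s)         # pre-standardized input
  expect_all_close(sc_raw, sc_std, 1e-8)
})

test_that("upper tercile flag: exact terciles, ties, 368-patient case", {
  expect_equal(which(upper_tercile_flag(1:9)), c(7L, 8L, 9L))
  expect_false(any(upper_tercile_flag(rep(2, 10))))
  expect_error(upper_tercile_flag(c(1, 2)), "at least 3")

  set.seed(44)
  x <- rnorm(368)  # distinct values
  flags <- upper_tercile_flag(x)
  # brute-force oracle: values strictly above the interpolated 2/3
  # quantile are ranks 246..368, i.e. ceiling(368/3) = 123 patients
  q <- sort(x)[245] + (2 / 3 * 367 + 1 - 245) * (sort(x)[246] - sort(x)[245])
  expect_equal(sum(flags), sum(x > q))
  expect_equal(sum(flags), 123L)
  expect_true(all(x[flags] > q) && all(x[!flags] <= q))
})

test_that("PCA model JSON round trip preserves the model", {
  ft <- simulate_feature_table(120, seed = 8)
  s <- standardize_features(as.matrix(ft$features[, -1]))
  model <- fit_pca(s, k = 3)
  model$center <- attr(s, "center"); model$scale <- attr(s, "scale")
  path <- tempfile(fileext = ".json")
  write_pca_json(model, path)
  back <- read_pca_json(path)
  expect_all_close(back$loadings, model$loadings, 1e-12)
  expect_all_close(back$explained_variance, model$explained_variance, 1e-12)
  expect_equal(back$orientation_reference, model$orientation_reference)
  fm <- as.matrix(ft$features[, -1])
  expect_all_close(cp_scores(back, fm), cp_scores(model, fm), 1e-10)
})
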