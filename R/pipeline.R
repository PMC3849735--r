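# End-to-end pipeline: slides -> features -> composite scores ->
# survival model. Two stages mirror the analysis: heavy per-slide image
# processing (run_slide) and fast per-cohort statistics (run_cohort).

#' Pipeline configuration
#'
#' All tunable parameters of the pipeline with their defaults; validated
#' on construction and round-trippable through JSON.
#'
#' @param native_resolution Scan resolution, um/px (default 0.5).
#' @param decimation_levels Wavelet halving levels to reach the working
#'   resolution (default 3: 0.5 -> 4 um/px).
#' @param min_area,max_area Nucleus size filter, um^2.
#' @param stain_threshold DAB OD threshold; `NULL` = Otsu per slide.
#' @param quadrat_side Quadrat side, um (default 200).
#' @param glcm_levels,glcm_symmetric GLCM quantization levels and
#'   symmetry flag.
#' @param pca_k Number of composite components (default 3).
#' @param r_max Redundancy threshold for feature selection.
#' @param orientation_reference Feature fixing component signs.
#' @param selected_features Optional explicit feature subset, bypassing
#'   greedy selection.
#' @param mitotic_cut Risk-model mitotic index cut (strict >).
#' @param ties Cox tie handling.
#' @param hot_spot_percentile,hot_spot_min_cluster Hot-spot parameters.
#' @param risk_component Composite score binarized by upper tercile in
#'   the risk model (default `"CP2"`).
#' @param seed Base seed for stochastic stages.
#' @return Object of class `"pipeline_config"` (a validated list).
#' @export
pipeline_config <- function(native_resolution = 0.5,
                            decimation_levels = 3,
                            min_area = 4, max_area = 1000,
                            stain_threshold = NULL,
                            quadrat_side = 200,
                            glcm_levels = 16, glcm_symmetric = TRUE,
                            pca_k = 3, r_max = 0.8,
                            orientation_reference = "fisher_index",
                            selected_features = NULL,
                            mitotic_cut = 10,
                            ties = "efron",
                            hot_spot_percentile = 10,
                            hot_spot_min_cluster = 5,
                            risk_component = "CP2",
                            seed = 1L) {
  cfg <- list(native_resolution = native_resolution,
              decimation_levels = as.integer(decimation_levels),
              min_area = min_area, max_area = max_area,
              stain_threshold = stain_threshold,
              quadrat_side = quadrat_side,
              glcm_levels = as.integer(glcm_levels),
              glcm_symmetric = isTRUE(glcm_symmetric),
              pca_k = as.integer(pca_k), r_max = r_max,
              orientation_reference = orientation_reference,
              selected_features = selected_features,
              mitotic_cut = mitotic_cut,
              ties = match.arg(ties, c("efron", "breslow")),
              hot_spot_percentile = hot_spot_percentile,
              hot_spot_min_cluster = hot_spot_min_cluster,
              risk_component = risk_component,
              seed = as.integer(seed))
  stopifnot(cfg$native_resolution > 0, cfg$decimation_levels >= 1,
            cfg$min_area >= 0, cfg$max_area > cfg$min_area,
            cfg$quadrat_side > 0, cfg$glcm_levels >= 2,
            cfg$pca_k >= 1, cfg$r_max > 0, cfg$r_max <= 1,
            cfg$mitotic_cut >= 0)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' @param cfg A [pipeline_config()].
#' @param path JSON file.
#' @export
write_config_json <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  jsonlite::write_json(unclass(cfg), path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, j[!vapply(j, is.null, logical(1))])
}

#' Names of the nine per-slide heterogeneity features
#'
#' @return Character vector of feature column names.
#' @export
heterogeneity_features <- function() {
  c("voronoi_variance", "fisher_index", "norm_density_variance",
    "haralick_energy", "haralick_correlation", "hot_spot_count",
    "quadrat_mean_density", "haralick_contrast", "haralick_entropy")
}

#' Process one slide into a feature row
#'
#' Runs the imaging chain on one stained slide: wavelet decimation to
#' the working resolution, nucleus detection at native resolution
#' within the ROI, spatial statistics on the detected pattern (Voronoi
#' pavement variance, quadrat dispersion indices, hot spots) and
#' Haralick texture on the decimated image. Deterministic: identical
#' inputs and configuration give an identical row.
#'
#' @param cfg A [pipeline_config()].
#' @param image Path to the slide image (PNG/TIFF) or a
#'   [virtual_slide()].
#' @param roi Path to an ROI file ([read_roi()]), an [roi_mask()], or
#'   `NULL` for the full frame.
#' @param slide_id Identifier written into the row.
#' @param verbose Log stages to stderr.
#' @return One-row `data.frame`: `id`, `n_nuclei`, `mitotic_index`,
#'   and the nine heterogeneity features.
#' @export
run_slide <- function(cfg, image, roi = NULL, slide_id = "slide",
                      verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  slide <- if (inherits(image, "virtual_slide")) image
           else read_slide(image, cfg$native_resolution)
  d <- slide_dim(slide)
  say("[%s] slide %d x %d px at %.3g um/px", slide_id, d[2], d[1],
      slide$resolution)
  if (is.character(roi)) {
    if (!file.exists(roi)) stop("ROI file not found: ", roi)
    roi <- read_roi(roi, slide$resolution)
  }
  if (is.null(roi)) {
    w <- d[2] * slide$resolution; h <- d[1] * slide$resolution
    roi <- roi_mask(polygon = rect_polygon(w, h))
  }
  # region for spatial statistics: polygon ROI when available, else the
  # full frame rectangle (points are still filtered by the raster mask)
  w <- d[2] * slide$resolution; h <- d[1] * slide$resolution
  reg <- if (roi$type == "polygon") region(w, h, roi$polygon)
         else region(w, h)
  area_mm2 <- if (roi$type == "polygon") polygon_area(roi$polygon) / 1e6
              else roi_mask_area_mm2(roi)

  work <- decimate_wavelet(slide, cfg$decimation_levels)
  say("[%s] decimated %d levels -> %.3g um/px", slide_id,
      cfg$decimation_levels, work$resolution)

  nuclei <- detect_positive_nuclei(slide, mask = roi,
                                   min_area = cfg$min_area,
                                   max_area = cfg$max_area,
                                   stain_threshold = cfg$stain_threshold)
  say("[%s] detected %d nuclei (threshold %.4g)", slide_id, nrow(nuclei),
      attr(nuclei, "threshold"))
  pattern <- point_pattern(nuclei$x_um, nuclei$y_um, reg)
  if (roi$type == "raster") {
    keep <- roi_contains(roi, pattern$x, pattern$y)
    pattern$x <- pattern$x[keep]; pattern$y <- pattern$y[keep]
  }
  mi <- compute_mitotic_index(npoints(pattern), area_mm2)

  qc <- quadrat_counts(pattern, cfg$quadrat_side)
  fi <- fisher_index(qc)
  ndv <- normalized_density_variance(qc)
  dens <- qc$count[qc$retained] / qc$overlap_um2[qc$retained] * 1e6
  tess <- voronoi_tessellation(pattern, reg)
  vv <- voronoi_area_variance(tess, normalized = TRUE)
  hs <- detect_hot_spots(tess, cfg$hot_spot_percentile,
                         cfg$hot_spot_min_cluster)
  q <- quantize_image(work, cfg$glcm_levels, mask = roi)
  g <- compute_glcm(q, symmetric = cfg$glcm_symmetric)
  ext <- haralick_extended(g)
  say("[%s] features done (quadrats %d, hot spots %d)", slide_id,
      sum(qc$retained), length(hs))
  data.frame(id = slide_id, n_nuclei = npoints(pattern),
             mitotic_index = mi,
             voronoi_variance = vv, fisher_index = fi,
             norm_density_variance = ndv,
             haralick_energy = haralick_energy(g),
             haralick_correlation = haralick_correlation(g),
             hot_spot_count = length(hs),
             quadrat_mean_density = mean(dens),
             haralick_contrast = unname(ext["contrast"]),
             haralick_entropy = unname(ext["entropy"]))
}

#' Cohort-level analysis: composite scores and prognostic models
#'
#' Joins the per-slide feature table to the clinical cohort on `id`,
#' standardizes the heterogeneity features, prunes redundant ones,
#' fits the PCA, computes CP scores and the upper-tercile flag of the
#' risk component, screens features univariately, fits the multivariate
#' Cox model and the three-poor-factor risk groups, and writes all
#' artifacts (with a checksum manifest) to `out_dir`.
#'
#' @param cfg A [pipeline_config()].
#' @param features Feature table (data.frame or CSV path) with `id` and
#'   the heterogeneity feature columns.
#' @param cohort Cohort table (data.frame or CSV path) with `id`,
#'   `time`, `event`, `mitotic_index`, `node_pos`.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @return List with `features_selected`, `pca`, `scores` (data.frame
#'   id, CP1..CPk, cp_upper_tercile), `univariate`, `cox`,
#'   `risk_groups`, `risk_logrank`, `km_curves`, `manifest`.
#' @export
run_cohort <- function(cfg, features, cohort, out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.character(features)) features <- utils::read.csv(features)
  if (is.character(cohort)) cohort <- utils::read.csv(cohort)
  unmatched <- setdiff(cohort$id, features$id)
  if (length(unmatched))
    stop("cohort ids missing from the feature table: ",
         paste(utils::head(unmatched, 10), collapse = ", "))
  features <- features[match(cohort$id, features$id), , drop = FALSE]

  fcols <- intersect(heterogeneity_features(), names(features))
  if (length(fcols) < 2L) stop("too few heterogeneity feature columns")
  fm <- as.matrix(features[, fcols])
  std <- standardize_features(fm)
  sel <- cfg$selected_features %||% select_nonredundant(std, cfg$r_max)
  sel <- intersect(colnames(std), sel)
  orient <- if (cfg$orientation_reference %in% sel)
    cfg$orientation_reference else sel[1]
  model <- fit_pca(std[, sel, drop = FALSE], k = min(cfg$pca_k, length(sel)),
                   orientation_reference = orient)
  model$center <- attr(std, "center")[sel]
  model$scale <- attr(std, "scale")[sel]
  sc <- cp_scores(model, fm[, sel, drop = FALSE])
  risk_cp <- cfg$risk_component
  if (!risk_cp %in% colnames(sc)) risk_cp <- colnames(sc)[ncol(sc)]
  flags <- upper_tercile_flag(sc[, risk_cp])
  scores <- data.frame(id = cohort$id, sc, cp_upper_tercile = flags)

  cohort2 <- cbind(cohort[setdiff(names(cohort), colnames(sc))], sc)
  if (!"mitotic_high" %in% names(cohort2))
    cohort2$mitotic_high <- as.integer(cohort2$mitotic_index >
                                         cfg$mitotic_cut)
  screen_feats <- c(fcols, colnames(sc))
  features_joined <- cbind(cohort2[c("time", "event")],
                           as.data.frame(fm), as.data.frame(sc))
  uni <- univariate_screen(features_joined, screen_feats)
  cox <- cox_fit(cohort2, c(risk_cp, "mitotic_high", "node_pos"),
                 ties = cfg$ties)
  rg <- assign_risk_groups(cohort2, mitotic_cut = cfg$mitotic_cut,
                           cp2_flags = flags)
  rg$id <- cohort2$id
  lr <- logrank_test(cohort2$time, cohort2$event, rg$group)
  km <- do.call(rbind, lapply(levels(rg$group), function(g) {
    i <- rg$group == g
    if (!any(i)) return(NULL)
    cbind(group = g, as.data.frame(km_estimate(cohort2$time[i],
                                               cohort2$event[i])))
  }))
  out <- list(features_selected = sel, pca = model, scores = scores,
              univariate = uni, cox = cox, risk_groups = rg,
              risk_logrank = lr, km_curves = km, manifest = NULL)
  if (!is.null(out_dir)) out$manifest <- write_cohort_outputs(out, out_dir)
  out
}

write_cohort_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  utils::write.csv(res$scores, p("cp_scores.csv"), row.names = FALSE)
  utils::write.csv(res$univariate, p("univariate.csv"), row.names = FALSE)
  utils::write.csv(res$cox$coefficients, p("cox_fit.csv"),
                   row.names = FALSE)
  utils::write.csv(res$risk_groups, p("risk_groups.csv"),
                   row.names = FALSE)
  utils::write.csv(res$km_curves, p("km_curves.csv"), row.names = FALSE)
  write_pca_json(res$pca, p("pca_model.json"))
  jsonlite::write_json(list(selected_features = res$features_selected,
                            risk_logrank = res$risk_logrank),
                       p("selection.json"), digits = NA,
                       auto_unbox = TRUE)
  files <- c("cp_scores.csv", "univariate.csv", "cox_fit.csv",
             "risk_groups.csv", "km_curves.csv", "pca_model.json",
             "selection.json")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir,
                                                              files))))
  jsonlite::write_json(manifest, p("manifest.json"), digits = NA)
  manifest
}

#' Simulate a per-patient heterogeneity feature table
#'
#' Latent-factor model for the nine heterogeneity features: four
#' independent latent sources with decreasing variance are mixed by a
#' fixed orthogonal matrix into four latent axes, and each feature is a
#' noisy copy of one axis (groups of 3/3/2/1 features). The source with
#' the second-largest variance is the "true heterogeneity" score
#' returned as `h_true`; by construction the second principal component
#' of the selected features recovers it.
#'
#' @param n Number of patients.
#' @param seed Integer seed.
#' @param noise_sd Feature noise standard deviation (latents have
#'   variance about 1).
#' @return List with `features` (data.frame `id` + nine columns) and
#'   `h_true` (standardized latent heterogeneity).
#' @export
simulate_feature_table <- function(n, seed, noise_sd = 0.3) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  src_var <- c(1.8, 1.4, 0.55, 0.25)
  z <- matrix(stats::rnorm(n * 4), n, 4)
  s <- sweep(z, 2, sqrt(src_var), "*")
  Q <- matrix(c(1, 1, 1, 1,
                1, -1, 1, -1,
                1, 1, -1, -1,
                1, -1, -1, 1) / 2, 4, 4, byrow = TRUE)
  latents <- s %*% t(Q)   # n x 4 latent axes, unit variance each
  groups <- c(quadrat_mean_density = 1, hot_spot_count = 1,
              haralick_entropy = 1,
              fisher_index = 3, voronoi_variance = 3,
              norm_density_variance = 3,
              haralick_correlation = 2, haralick_contrast = 2,
              haralick_energy = 4)
  f <- sapply(groups, function(g)
    latents[, g] + stats::rnorm(n, 0, noise_sd))
  colnames(f) <- names(groups)
  list(features = data.frame(id = seq_len(n),
                             f[, heterogeneity_features()]),
       h_true = s[, 2] / sqrt(src_var[2]))
}

#' Generate the synthetic demo dataset
#'
#' Writes (a) `n_slides` synthetic stained slides spanning homogeneous
#' (CSR) to strongly clustered patterns, each with its ROI polygon and
#' the ground-truth pattern CSV, and (b) a synthetic cohort of
#' `n_patients` with a per-patient heterogeneity feature table whose
#' latent heterogeneity drives the hazard together with mitotic index
#' and nodal status.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param n_slides Number of slides (default 40).
#' @param n_patients Cohort size (default 368, the familiar series
#'   size).
#' @param cfg A [pipeline_config()]; `native_resolution` sets the
#'   rendered pixel size.
#' @param slide_extent_um Side of the square slides, um (default 1000).
#' @param intensity Mean nucleus intensity per mm^2 on the slides
#'   (default 150; elevated so that spatial statistics are informative
#'   on the compact demo extent).
#' @return Invisibly, a list with the written paths and the simulation
#'   truth.
#' @export
make_demo <- function(out_dir, seed = 1L, n_slides = 40,
                      n_patients = 368, cfg = pipeline_config(),
                      slide_extent_um = 1000, intensity = 150) {
  dir.create(file.path(out_dir, "slides"), showWarnings = FALSE,
             recursive = TRUE)
  reg <- region(slide_extent_um, slide_extent_um)
  # clustering weight ramps 0 -> 1 across slides
  wts <- if (n_slides == 1L) 0.5 else
    seq(0, 1, length.out = n_slides)
  truth <- data.frame(id = sprintf("slide%03d", seq_len(n_slides)),
                      cluster_weight = wts, n_points = NA_integer_)
  slide_paths <- character(n_slides)
  for (i in seq_len(n_slides)) {
    s_i <- seed + 1000L + i
    p_csr <- generate_csr_pattern(intensity * (1 - wts[i]), reg, s_i)
    pat <- p_csr
    if (wts[i] > 0) {
      spec <- cluster_spec(parent_intensity = intensity * wts[i] / 12,
                           offspring_mean = 12, offspring_sd = 40)
      p_cl <- generate_clustered_pattern(spec, reg, s_i + 500L)
      pat <- point_pattern(c(p_csr$x, p_cl$x), c(p_csr$y, p_cl$y), reg)
    }
    truth$n_points[i] <- npoints(pat)
    sl <- render_slide(pat, cfg$native_resolution, nucleus_radius = 3,
                       stain_contrast = 0.9, noise_sd = 3, seed = s_i)
    slide_paths[i] <- file.path(out_dir, "slides",
                                paste0(truth$id[i], ".png"))
    write_slide(sl, slide_paths[i])
    write_roi_csv(roi_mask(polygon = reg$roi),
                  file.path(out_dir, "slides",
                            paste0(truth$id[i], "_roi.csv")))
    write_pattern_csv(pat, file.path(out_dir, "slides",
                                     paste0(truth$id[i], "_truth.csv")))
  }
  utils::write.csv(truth, file.path(out_dir, "slides_truth.csv"),
                   row.names = FALSE)
  ft <- simulate_feature_table(n_patients, seed + 77L)
  cohort <- generate_cohort(cohort_spec(n = n_patients), seed + 99L,
                            cp2 = ft$h_true)
  utils::write.csv(ft$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  write_config_json(cfg, file.path(out_dir, "config.json"))
  invisible(list(slides = slide_paths,
                 features_csv = file.path(out_dir, "features.csv"),
                 cohort_csv = file.path(out_dir, "cohort.csv"),
                 truth = truth, h_true = ft$h_true))
}
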