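# Feature reduction: select nonredundant heterogeneity features and
# combine them into composite scores CP1-CP3 via principal component
# analysis of the correlation matrix (the features carry incommensurable
# units, so columns are standardized first).

#' Standardize a feature matrix
#'
#' Each column is centred to zero mean and scaled to unit sample
#' standard deviation; the parameters are stored so new data can be
#' transformed consistently.
#'
#' @param mat Numeric matrix or data.frame, rows = slides/patients,
#'   named feature columns. No missing values allowed.
#' @return Standardized matrix with attributes `center` and `scale`.
#' @export
standardize_features <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("feature matrix contains missing values")
  ctr <- colMeans(mat)
  scl <- apply(mat, 2, stats::sd)
  bad <- which(scl <= 0 | !is.finite(scl))
  if (length(bad))
    stop("zero-variance feature column(s): ",
         paste(colnames(mat)[bad], collapse = ", "))
  out <- sweep(sweep(mat, 2, ctr), 2, scl, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' @rdname standardize_features
#' @param params A matrix previously returned by `standardize_features()`
#'   (its `center`/`scale` attributes are reused), or a list with
#'   `center` and `scale`.
#' @param newdata New rows with the same columns.
#' @export
apply_standardization <- function(params, newdata) {
  ctr <- attr(params, "center") %||% params$center
  scl <- attr(params, "scale") %||% params$scale
  nd <- as.matrix(newdata)[, names(ctr), drop = FALSE]
  sweep(sweep(nd, 2, ctr), 2, scl, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select nonredundant features by greedy correlation pruning
#'
#' While any pair of surviving features has absolute Pearson correlation
#' above `r_max`, the member of the worst pair with the larger mean
#' absolute correlation to all other survivors is dropped. Deterministic
#' for distinct correlations; ties break toward keeping the
#' earlier-named column.
#'
#' @param mat Feature matrix (rows = observations).
#' @param r_max Correlation threshold (default 0.8).
#' @return Character vector of surviving feature names, in original
#'   column order.
#' @export
select_nonredundant <- function(mat, r_max = 0.8) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) return(colnames(mat))
  keep <- colnames(mat)
  r <- abs(stats::cor(mat))
  diag(r) <- 0
  while (length(keep) > 1L) {
    rk <- r[keep, keep, drop = FALSE]
    mx <- max(rk)
    if (mx <= r_max) break
    w <- which(rk == mx, arr.ind = TRUE)[1, ]
    pair <- keep[w]
    mean_abs <- rowMeans(rk[pair, , drop = FALSE])
    drop <- pair[which.max(mean_abs)]
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Principal component analysis for composite heterogeneity scores
#'
#' Eigen-decomposition of the correlation matrix of the (standardized)
#' selected features. The first `k` components are named CP1..CPk;
#' loadings are orthonormal and explained variance is non-increasing.
#' Signs are fixed by [orient_components()] so that a higher score means
#' more heterogeneity.
#'
#' @param mat Standardized feature matrix ([standardize_features()]).
#' @param k Number of components to keep (default 3).
#' @param orientation_reference Feature whose loading fixes each
#'   component's sign (default `"fisher_index"` when present, else the
#'   first column).
#' @return Object of class `"pca_model"`: `loadings` (feature x
#'   component), `explained_variance`, `explained_ratio`, `center`,
#'   `scale`, `orientation_reference`.
#' @export
fit_pca <- function(mat, k = 3, orientation_reference = NULL) {
  mat <- as.matrix(mat)
  if (k > ncol(mat)) stop("k exceeds the number of features")
  if (nrow(mat) <= ncol(mat))
    stop("need more observations than features")
  cm <- stats::cor(mat)
  eg <- eigen(cm, symmetric = TRUE)
  load <- eg$vectors[, seq_len(k), drop = FALSE]
  rownames(load) <- colnames(mat)
  colnames(load) <- paste0("CP", seq_len(k))
  if (is.null(orientation_reference))
    orientation_reference <- if ("fisher_index" %in% colnames(mat))
      "fisher_index" else colnames(mat)[1]
  model <- structure(list(loadings = load,
                          explained_variance = eg$values[seq_len(k)],
                          explained_ratio = eg$values[seq_len(k)] /
                            sum(eg$values),
                          center = attr(mat, "center"),
                          scale = attr(mat, "scale"),
                          orientation_reference = orientation_reference),
                     class = "pca_model")
  orient_components(model, orientation_reference)
}

#' Fix the sign of each principal component
#'
#' A principal direction is defined up to sign; each component is
#' flipped so its loading on the reference feature is non-negative,
#' making "higher score = more heterogeneity" hold when the reference is
#' a heterogeneity index. Idempotent; explained variance is unchanged.
#' A zero loading on the reference leaves the sign as-is with a warning.
#'
#' @param model A `"pca_model"`.
#' @param reference Feature name present in the loadings.
#' @return The re-oriented model.
#' @export
orient_components <- function(model, reference = model$orientation_reference) {
  stopifnot(inherits(model, "pca_model"))
  if (!reference %in% rownames(model$loadings))
    stop("reference feature not in the model: ", reference)
  ref <- model$loadings[reference, ]
  if (any(ref == 0))
    warning("zero loading on reference feature for component(s): ",
            paste(colnames(model$loadings)[ref == 0], collapse = ", "))
  flip <- ifelse(ref < 0, -1, 1)
  model$loadings <- sweep(model$loadings, 2, flip, "*")
  model$orientation_reference <- reference
  model
}

#' @export
print.pca_model <- function(x, ...) {
  cat("pca_model:", ncol(x$loadings), "components over",
      nrow(x$loadings), "features\n")
  cat("explained variance ratio:",
      sprintf("%.3f", x$explained_ratio), "\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Composite scores CP1..CPk for a feature matrix
#'
#' Projects (already standardized, or raw if the model stores
#' standardization parameters) feature rows onto the model loadings.
#'
#' @param model A `"pca_model"`.
#' @param mat Feature matrix; if the model has `center`/`scale`, raw
#'   features are standardized first.
#' @return Matrix of scores, columns CP1..CPk.
#' @export
cp_scores <- function(model, mat) {
  stopifnot(inherits(model, "pca_model"))
  mat <- as.matrix(mat)[, rownames(model$loadings), drop = FALSE]
  if (!is.null(model$center))
    mat <- sweep(sweep(mat, 2, model$center[rownames(model$loadings)]),
                 2, model$scale[rownames(model$loadings)], "/")
  mat %*% model$loadings
}

#' Flag the upper tercile of a score
#'
#' TRUE where the score strictly exceeds the empirical 2/3 quantile
#' (linear-interpolation, type 7); ties at the cutpoint are not flagged.
#' With distinct values this flags ceiling(n/3) or floor(n/3)
#' observations.
#'
#' @param scores Numeric vector, length >= 3.
#' @return Logical vector.
#' @export
upper_tercile_flag <- function(scores) {
  if (length(scores) < 3L) stop("need at least 3 scores")
  if (anyNA(scores)) stop("scores contain missing values")
  scores > stats::quantile(scores, 2 / 3, type = 7, names = FALSE)
}

#' Serialize / restore a PCA model as JSON
#'
#' @param model A `"pca_model"`.
#' @param path JSON file path.
#' @export
write_pca_json <- function(model, path) {
  jsonlite::write_json(list(
    features = rownames(model$loadings),
    components = colnames(model$loadings),
    loadings = unname(model$loadings),
    explained_variance = model$explained_variance,
    explained_ratio = model$explained_ratio,
    center = as.list(model$center %||% NULL),
    scale = as.list(model$scale %||% NULL),
    orientation_reference = model$orientation_reference),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pca_json
#' @export
read_pca_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  load <- matrix(as.numeric(j$loadings), nrow = length(j$features),
                 dimnames = list(j$features, j$components))
  structure(list(loadings = load,
                 explained_variance = j$explained_variance,
                 explained_ratio = j$explained_ratio,
                 center = if (length(j$center)) unlist(j$center) else NULL,
                 scale = if (length(j$scale)) unlist(j$scale) else NULL,
                 orientation_reference = j$orientation_reference),
            class = "pca_model")
}
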