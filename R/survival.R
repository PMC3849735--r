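# Prognostic layer: Kaplan-Meier estimation, log-rank screening, Cox
# proportional-hazards regression (partial likelihood, Efron ties) and
# the three-poor-factor risk-group model. Estimation is delegated to
# the survival package; this layer fixes the interfaces, the event
# definitions and the grouping rule, and exposes an explicit partial
# log-likelihood for diagnostics.

#' Kaplan-Meier estimate of disease-free survival
#'
#' Product-limit estimator as a right-continuous step function starting
#' at 1.
#'
#' @param times Positive follow-up times.
#' @param events Event indicators (1 = oncological event, 0 = censored).
#' @return Object of class `"km_curve"`: data.frame with columns
#'   `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop("no observations")
  if (any(!is.finite(times) | times <= 0))
    stop("times must be positive and finite")
  stopifnot(length(times) == length(events), all(events %in% 0:1))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param km A [km_estimate()] result.
#' @param t Times at which to evaluate S(t).
#' @return Survival probabilities (1 before the first event time).
#' @export
km_surv <- function(km, t) {
  stopifnot(inherits(km, "km_curve"))
  idx <- findInterval(t, km$time)
  c(1, km$surv)[idx + 1L]
}

#' Log-rank test across groups
#'
#' @param times,events As in [km_estimate()].
#' @param groups Group labels; at least two nonempty groups.
#' @return List with `statistic` (chi-square), `df`, `p`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L)
    stop("need at least 2 nonempty groups")
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(fit$n) - 1L
  list(statistic = fit$chisq, df = df,
       p = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood over the named covariates
#' (Efron tie handling by default, Newton-type iteration) and reports
#' coefficients, hazard ratios, standard errors from the observed
#' information, and Wald p-values.
#'
#' @param cohort Data frame with columns `time`, `event` and the
#'   covariates.
#' @param covariates Character vector of covariate column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return Object of class `"cox_fit"`: data.frame `coefficients`
#'   (term, beta, hr, se, z, p), plus `loglik`, `n`, `n_event`,
#'   `converged`, `ties`.
#' @export
cox_fit <- function(cohort, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  miss <- setdiff(c("time", "event", covariates), names(cohort))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(cohort[, c("time", "event", covariates)]))
    stop("missing values in modeled columns")
  if (sum(cohort$event) < 1L) stop("need at least one event")
  X <- as.matrix(cohort[, covariates, drop = FALSE])
  if (qr(stats::cov(X))$rank < ncol(X))
    stop("collinear covariates: ", paste(covariates, collapse = ", "))
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(covariates, collapse = " + ")))
  fit <- survival::coxph(f, data = cohort, ties = ties,
                         control = survival::coxph.control(iter.max = 100))
  if (is.null(fit$coefficients) || anyNA(fit$coefficients))
    stop("Cox fit failed to converge")
  s <- summary(fit)
  co <- data.frame(term = covariates,
                   beta = unname(s$coefficients[, "coef"]),
                   hr = exp(unname(s$coefficients[, "coef"])),
                   se = unname(s$coefficients[, "se(coef)"]),
                   z = unname(s$coefficients[, "z"]),
                   p = unname(s$coefficients[, "Pr(>|z|)"]))
  structure(list(coefficients = co,
                 loglik = fit$loglik[2],
                 n = s$n, n_event = fit$nevent,
                 converged = fit$iter < 100, ties = ties),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit (%s ties): n=%d, events=%d, logPL=%.4f\n",
              x$ties, x$n, x$n_event, x$loglik))
  print(transform(x$coefficients,
                  beta = round(beta, 4), hr = round(hr, 3),
                  se = round(se, 4), z = round(z, 3),
                  p = signif(p, 3)))
  invisible(x)
}

#' Cox partial log-likelihood and score (Efron or Breslow ties)
#'
#' Explicit evaluation of the partial log-likelihood at a given
#' coefficient vector, used to verify fits (the score should vanish at
#' the maximum).
#'
#' @param beta Coefficient vector.
#' @param time,event,X Data: times, 0/1 events, covariate matrix.
#' @param ties `"efron"` or `"breslow"`.
#' @return List with `loglik` and `score` (gradient vector).
#' @export
cox_partial_loglik <- function(beta, time, event, X,
                               ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  ll <- 0
  sc <- numeric(length(beta))
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)   # tied deaths at t
    R <- which(time >= t)                # risk set
    d <- length(D)
    sw_R <- sum(w[R])
    sx_R <- colSums(X[R, , drop = FALSE] * w[R])
    sw_D <- sum(w[D])
    sx_D <- colSums(X[D, , drop = FALSE] * w[D])
    ll <- ll + sum(eta[D])
    for (l in seq_len(d)) {
      frac <- if (ties == "efron") (l - 1) / d else 0
      denom <- sw_R - frac * sw_D
      num <- sx_R - frac * sx_D
      ll <- ll - log(denom)
      sc <- sc - num / denom
    }
    sc <- sc + colSums(X[D, , drop = FALSE])
  }
  list(loglik = ll, score = sc)
}

#' Assign three-poor-factor risk groups
#'
#' Counts the poor-prognosis factors of the multivariate model per
#' patient: mitotic index strictly above the cut (default 10 per
#' 1.7 mm^2), axillary lymph-node involvement, and upper-tercile CP2.
#' Patients are grouped as 0 factors / 1 or 2 factors / 3 factors.
#'
#' @param cohort Data frame with `mitotic_index` and `node_pos`.
#' @param mitotic_cut Threshold; the comparison is strict (`>`).
#' @param cp2_flags Logical vector: upper-tercile CP2 indicator (from
#'   [upper_tercile_flag()]); defaults to computing it from a `cp2`
#'   column.
#' @return `data.frame` with `factor_count` (0-3) and `group` (factor
#'   with levels `"0 factor"`, `"1 or 2 factors"`, `"3 factors"`).
#' @export
assign_risk_groups <- function(cohort, mitotic_cut = 10, cp2_flags = NULL) {
  need <- c("mitotic_index", "node_pos")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("missing covariate(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(cp2_flags)) {
    if (!"cp2" %in% names(cohort)) stop("missing covariate(s): cp2")
    cp2_flags <- upper_tercile_flag(cohort$cp2)
  }
  if (anyNA(cohort$mitotic_index) || anyNA(cohort$node_pos) ||
      anyNA(cp2_flags))
    stop("missing values in risk-model covariates")
  fc <- as.integer(cohort$mitotic_index > mitotic_cut) +
        as.integer(cohort$node_pos > 0) +
        as.integer(cp2_flags)
  group <- cut(fc, breaks = c(-0.5, 0.5, 2.5, 3.5),
               labels = c("0 factor", "1 or 2 factors", "3 factors"))
  data.frame(factor_count = fc, group = group)
}

#' Univariate screening of prognostic features
#'
#' Binary or categorical features (factors, or <= 5 distinct values)
#' are tested by log-rank across their levels; continuous features by a
#' univariate Cox Wald test. Constant features are skipped with a
#' warning.
#'
#' @param cohort Data frame with `time`, `event` and the features.
#' @param features Character vector of feature columns.
#' @return `data.frame` with columns `feature`, `method`, `statistic`,
#'   `p`; one row per screened feature.
#' @export
univariate_screen <- function(cohort, features) {
  miss <- setdiff(features, names(cohort))
  if (length(miss)) stop("features not in cohort: ",
                         paste(miss, collapse = ", "))
  rows <- lapply(features, function(f) {
    v <- cohort[[f]]
    if (length(unique(v)) < 2L) {
      warning("constant feature skipped: ", f)
      return(NULL)
    }
    if (is.factor(v) || is.character(v) || length(unique(v)) <= 5L) {
      lr <- logrank_test(cohort$time, cohort$event, v)
      data.frame(feature = f, method = "logrank",
                 statistic = lr$statistic, p = lr$p)
    } else {
      cf <- cox_fit(cohort, f)
      data.frame(feature = f, method = "cox_wald",
                 statistic = cf$coefficients$z^2, p = cf$coefficients$p)
    }
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
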