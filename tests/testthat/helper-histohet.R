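# Shared builders and independent oracles for the test suite.

# a 1 mm^2 square region
mm_region <- function(side_um = 1000) region(side_um, side_um)

# regular k x k lattice pattern centred in the region
lattice_pattern <- function(k, reg = mm_region()) {
  step_x <- reg$width / k; step_y <- reg$height / k
  g <- expand.grid(i = seq_len(k), j = seq_len(k))
  point_pattern((g$i - 0.5) * step_x, (g$j - 0.5) * step_y, reg)
}

# non-overlapping jittered grid pattern (for render/detect round trips)
jittered_grid_pattern <- function(k, reg = mm_region(), spacing_frac = 0.25,
                                  seed = 1) {
  set.seed(seed)
  step <- reg$width / k
  g <- expand.grid(i = seq_len(k), j = seq_len(k))
  point_pattern((g$i - 0.5) * step + runif(k^2, -1, 1) * step * spacing_frac,
                (g$j - 0.5) * step + runif(k^2, -1, 1) * step * spacing_frac,
                reg)
}

# brute-force GLCM oracle: double loop over pixels and offsets
brute_glcm <- function(q, offsets, symmetric = TRUE) {
  G <- attr(q, "levels")
  counts <- matrix(0, G, G)
  nr <- nrow(q); nc <- ncol(q)
  for (o in seq_len(nrow(offsets))) {
    dx <- offsets[o, 1]; dy <- offsets[o, 2]
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      r2 <- r + dy; c2 <- c + dx
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (is.na(q[r, c]) || is.na(q[r2, c2])) next
      counts[q[r, c], q[r2, c2]] <- counts[q[r, c], q[r2, c2]] + 1
    }
  }
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

# hand product-limit estimator (independent of survival::survfit)
brute_km <- function(times, events) {
  et <- sort(unique(times[events == 1]))
  s <- 1
  surv <- numeric(length(et))
  for (i in seq_along(et)) {
    at_risk <- sum(times >= et[i])
    d <- sum(times == et[i] & events == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = et, surv = surv)
}

# written-out Cox partial log-likelihood for untied data (oracle for
# small fits; independent of both coxph and cox_partial_loglik)
brute_cox_loglik_noties <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
  }
  ll
}

expect_all_close <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(a - b)), tol)
}
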