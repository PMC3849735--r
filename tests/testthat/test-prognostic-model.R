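test_that("Kaplan-Meier: closed forms and product-limit oracle", {
  # no events: S(t) = 1 everywhere
  km0 <- km_estimate(c(3, 5, 9), c(0, 0, 0))
  expect_true(all(km_surv(km0, c(1, 4, 10)) == 1))

  # two patients, events at t = 1 and 2: S = 1, 1/2, 0
  km2 <- km_estimate(c(1, 2), c(1, 1))
  expect_equal(km_surv(km2, c(0.5, 1.5, 2.5)), c(1, 0.5, 0))

  # 10-patient mixed censored fixture vs the hand product-limit formula
  times <- c(1, 2, 2, 3, 4, 5, 5, 6, 8, 9)
  events <- c(1, 1, 0, 1, 0, 1, 1, 0, 1, 0)
  km <- km_estimate(times, events)
  oracle <- brute_km(times, events)
  expect_equal(km_surv(km, oracle$time), oracle$surv, tolerance = 1e-12)

  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("log-rank: null identity, power, 2x2 algebraic reduction", {
  t0 <- c(1, 3, 4, 6, 8); e0 <- c(1, 0, 1, 1, 0)
  lr <- logrank_test(c(t0, t0), c(e0, e0), rep(1:2, each = 5))
  expect_lt(lr$statistic, 1e-10)
  expect_equal(lr$p, 1, tolerance = 1e-9)

  expect_error(logrank_test(t0, e0, rep(1, 5)), "2 nonempty")

  # hazard ratio 3, n = 200/arm, no censoring: overwhelming evidence
  set.seed(77)
  for (i in 1:10) {
    t1 <- rexp(200, 1); t2 <- rexp(200, 3)
    p <- logrank_test(c(t1, t2), rep(1, 400), rep(1:2, each = 200))$p
    expect_lt(p, 0.01)
  }

  # single event time: statistic = Pearson chi-square * (N-1)/N
  tm <- rep(1, 40); ev <- c(rep(1, 12), rep(0, 8), rep(1, 4), rep(0, 16))
  gr <- rep(1:2, each = 20)
  lr2 <- logrank_test(tm, ev, gr)
  chisq <- suppressWarnings(stats::chisq.test(table(gr, ev),
                                              correct = FALSE))$statistic
  expect_equal(lr2$statistic, unname(chisq) * 39 / 40, tolerance = 1e-9)
})

test_that("Cox fit: null recovery and brute-force likelihood oracle", {
  # covariate independent of survival
  set.seed(13)
  hits <- 0L
  for (i in 1:20) {
    n <- 1000
    d <- data.frame(time = rexp(n, 0.1), event = rbinom(n, 1, 0.8),
                    x = rnorm(n))
    b <- cox_fit(d, "x")$coefficients$beta
    hits <- hits + (abs(b) < 0.1)
  }
  expect_gte(hits, 18L)

  # 3-patient, 2-event, no-ties dataset against a written-out partial
  # likelihood maximized by brute force
  d3 <- data.frame(time = c(1, 2, 3), event = c(1, 1, 0),
                   x = c(0.5, -0.2, 0.3))
  fit <- cox_fit(d3, "x")
  opt <- stats::optimize(function(b)
    brute_cox_loglik_noties(b, d3$time, d3$event, d3$x),
    c(-10, 10), maximum = TRUE, tol = 1e-9)
  expect_equal(fit$coefficients$beta, opt$maximum, tolerance = 1e-4)
  expect_equal(fit$coefficients$hr, exp(fit$coefficients$beta))

  # score equation residual vanishes at the reported optimum
  co <- generate_cohort(cohort_spec(n = 400), 21)
  f <- cox_fit(co, c("cp2", "mitotic_high", "node_pos"))
  pl <- cox_partial_loglik(f$coefficients$beta, co$time, co$event,
                           as.matrix(co[, c("cp2", "mitotic_high",
                                            "node_pos")]))
  expect_lt(sqrt(sum(pl$score^2)), 1e-6)
  expect_equal(pl$loglik, f$loglik, tolerance = 1e-8)

  dup <- transform(co, cp2b = cp2)
  expect_error(cox_fit(dup, c("cp2", "cp2b")), "collinear")
  expect_error(cox_fit(co[0, ], "cp2"), "")
})

test_that("Efron and Breslow partial likelihoods match coxph exactly", {
  co <- generate_cohort(cohort_spec(n = 120), 3)
  co$time <- round(co$time)          # force ties
  co <- co[co$time > 0, ]
  X <- as.matrix(co[, c("cp2", "node_pos")])
  for (m in c("efron", "breslow")) {
    f <- cox_fit(co, c("cp2", "node_pos"), ties = m)
    pl <- cox_partial_loglik(f$coefficients$beta, co$time, co$event, X,
                             ties = m)
    expect_equal(pl$loglik, f$loglik, tolerance = 1e-8)
    expect_lt(sqrt(sum(pl$score^2)), 1e-5)
  }
})

test_that("risk groups implement the three-poor-factor rule", {
  pts <- data.frame(mitotic_index = c(12, 10, 25, 8),
                    node_pos = c(1, 0, 0, 1))
  flags <- c(TRUE, FALSE, FALSE, FALSE)
  rg <- assign_risk_groups(pts, mitotic_cut = 10, cp2_flags = flags)
  expect_equal(rg$factor_count, c(3L, 0L, 1L, 1L))
  expect_equal(as.character(rg$group),
               c("3 factors", "0 factor", "1 or 2 factors",
                 "1 or 2 factors"))
  # boundary: mitotic index exactly 10 does not count (strict >)
  expect_equal(rg$factor_count[2], 0L)

  co <- generate_cohort(cohort_spec(n = 300), 9)
  rg2 <- assign_risk_groups(co)
  expect_equal(sum(table(rg2$group)), 300L)  # partition
  expect_equal(rg2$factor_count,
               as.integer(co$mitotic_index > 10) + co$node_pos +
                 as.integer(upper_tercile_flag(co$cp2)))

  expect_error(assign_risk_groups(data.frame(mitotic_index = 1:5)),
               "node_pos")
})

test_that("risk groups are ordered beyond the early-noise region", {
  # with all three effects harmful, group survival separates cleanly at
  # the quartiles of follow-up
  ok <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_spec(n = 2000), s + 600)
    rg <- assign_risk_groups(co)
    probe <- stats::quantile(co$time, c(0.25, 0.5, 0.75))
    S <- sapply(levels(rg$group), function(g) {
      i <- rg$group == g
      km_surv(km_estimate(co$time[i], co$event[i]), probe)
    })
    all(S[, 1] > S[, 2]) && all(S[, 2] > S[, 3])
  }, logical(1))
  expect_gte(sum(ok), 19L)
})

test_that("univariate screen: completeness, power, null calibration", {
  co <- generate_cohort(cohort_spec(n = 300), 15)
  tab <- univariate_screen(co, c("cp2", "node_pos", "mitotic_index"))
  expect_equal(tab$feature, c("cp2", "node_pos", "mitotic_index"))
  expect_equal(tab$method[tab$feature == "node_pos"], "logrank")
  expect_equal(tab$method[tab$feature == "cp2"], "cox_wald")

  co$flat <- 1
  expect_warning(univariate_screen(co, c("cp2", "flat")), "constant")

  # a feature that truly drives the hazard (HR ~ 2) is detected
  set.seed(5)
  hits <- 0L
  for (i in 1:10) {
    d <- generate_cohort(cohort_spec(
      n = 500, log_hr = c(node_pos = log(2))), i)
    hits <- hits + (univariate_screen(d, "node_pos")$p < 0.05)
  }
  expect_gte(hits, 9L)

  # null features give roughly uniform p-values
  ps <- vapply(1:100, function(s) {
    d <- generate_cohort(cohort_spec(
      n = 100, log_hr = c(cp2 = 0)), s + 50)
    univariate_screen(d, "cp2")$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})
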