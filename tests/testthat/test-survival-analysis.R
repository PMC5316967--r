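test_that("Youden cutoff reproduces hand-worked examples", {
  yc <- youden_cutoff(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(yc$cutoff, 2.5)
  expect_equal(yc$j, 1)
  expect_identical(yc$direction, "high")

  yc2 <- youden_cutoff(c(1, 2, 3, 4, 5), c(0, 1, 0, 1, 1))
  expect_equal(yc2$cutoff, 3.5)
  expect_equal(yc2$j, 2 / 3)

  # direction flips when low expression is event-enriched
  yc3 <- youden_cutoff(c(1, 2, 3, 4), c(1, 1, 0, 0))
  expect_equal(yc3$cutoff, 2.5)
  expect_equal(yc3$j, 1)
  expect_identical(yc3$direction, "low")

  expect_error(youden_cutoff(c(1, 2, 3), c(1, 1, 1)), "both event classes")
  expect_error(youden_cutoff(c(2, 2, 2), c(0, 1, 1)), "distinct")
})

test_that("Youden cutoff equals the exhaustive-scan oracle", {
  set.seed(41)
  for (i in 1:500) {
    n <- sample(6:40, 1)
    values <- sample(1:12, n, replace = TRUE)  # plenty of ties
    events <- rbinom(n, 1, 0.5)
    if (length(unique(events)) < 2 || length(unique(values)) < 2) next
    got <- youden_cutoff(values, events)
    oracle <- youden_oracle(values, events)
    expect_equal(got$j, oracle$j, tolerance = 1e-12)
    expect_equal(got$cutoff, oracle$cutoff)
  }
})

test_that("Kaplan-Meier curve matches product-limit hand computations", {
  km <- km_curve(c(1, 2), c(1, 1))
  expect_equal(km$survival, c(0.5, 0))

  km2 <- km_curve(c(1, 2), c(1, 0))
  expect_equal(km2$survival[km2$time == 1], 0.5)
  expect_equal(min(km2$survival), 0.5)  # censoring leaves the curve flat

  km3 <- km_curve(c(3, 5, 7), c(0, 0, 0))
  expect_true(all(km3$survival == 1))

  expect_error(km_curve(numeric(), numeric()), "empty")
  expect_error(km_curve(c(0, 1), c(1, 1)), "positive")
})

test_that("KM curve is invariant under permutation of input rows", {
  set.seed(47)
  t <- rexp(40, 0.01); e <- rbinom(40, 1, 0.7)
  perm <- sample(40)
  expect_equal(km_curve(t, e), km_curve(t[perm], e[perm]))
})

test_that("log-rank reproduces the hand-worked example and null", {
  # A = (1,2) both events, B = (3,4) both events: O-E = 7/6, V = 17/36
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr$chi2, 49 / 17, tolerance = 1e-6)

  dup <- logrank_test(c(1, 2, 1, 2), c(1, 0, 1, 0), c(0, 0, 1, 1))
  expect_equal(dup$chi2, 0)
  expect_equal(dup$p_value, 1)

  expect_error(logrank_test(c(1, 2), c(1, 1), c("A", "A")), "two")
})

test_that("log-rank matches the textbook oracle and is label-symmetric", {
  set.seed(53)
  for (i in 1:30) {
    n <- sample(8:25, 1)
    t <- sample(1:15, n, replace = TRUE)
    e <- rbinom(n, 1, 0.7)
    g <- rbinom(n, 1, 0.5)
    if (length(unique(g)) < 2 || sum(e) == 0) next
    got <- logrank_test(t, e, g)
    oracle <- logrank_oracle(t, e, g)
    expect_equal(got$chi2, oracle$chi2, tolerance = 1e-10)
    expect_equal(logrank_test(t, e, 1 - g)$chi2, got$chi2, tolerance = 1e-10)
  }
})

test_that("Cox fit solves the analytic worked example", {
  # times 1..4 all events, alternating groups: score equation reduces to
  # u^2 - u - 4 = 0 with u = exp(beta), so HR = (1 + sqrt(17)) / 2
  fit <- cox_univariate(c(1, 2, 3, 4), c(1, 1, 1, 1), c(1, 0, 1, 0))
  expect_equal(fit$hazard_ratio, (1 + sqrt(17)) / 2, tolerance = 1e-6)
  expect_true(fit$estimable)
  expect_lte(fit$ci_low, fit$hazard_ratio)
  expect_gte(fit$ci_high, fit$hazard_ratio)
})

test_that("identical groups give unit hazard ratio", {
  t <- c(1, 2, 3, 1, 2, 3); e <- c(1, 0, 1, 1, 0, 1)
  fit <- cox_univariate(t, e, c(0, 0, 0, 1, 1, 1))
  expect_equal(fit$hazard_ratio, 1, tolerance = 1e-8)
  expect_equal(fit$wald_p, 1, tolerance = 1e-6)
})

test_that("monotone likelihood is reported as non-estimable", {
  # all group-1 events strictly precede all group-0 events, no censoring
  fit <- cox_univariate(c(1, 2, 3, 4, 5, 6), rep(1, 6), c(1, 1, 1, 0, 0, 0))
  expect_false(fit$estimable)
  expect_true(is.na(fit$hazard_ratio))
  expect_error(cox_univariate(c(1, 2), c(1, 1), c(1, 1)), "two levels")
})

test_that("Cox estimate maximizes the Efron partial likelihood (grid oracle)", {
  set.seed(59)
  grid <- seq(-3, 3, by = 1e-4)
  checked <- 0
  while (checked < 50) {
    n <- sample(8:14, 1)
    t <- sample(1:8, n, replace = TRUE)  # ties exercised
    e <- rbinom(n, 1, 0.75)
    g <- rbinom(n, 1, 0.5)
    if (length(unique(g)) < 2 || sum(e) < 2) next
    fit <- cox_univariate(t, e, g)
    if (!fit$estimable || abs(fit$beta) > 2.5) next
    ll <- efron_loglik(grid, t, e, g)
    beta_grid <- grid[which.max(ll)]
    expect_lt(abs(fit$beta - beta_grid), 2e-4)
    checked <- checked + 1
  }
})

test_that("exp(beta) converges to the true rate ratio without censoring", {
  g <- rep(0:1, each = 2500)
  cl <- simulate_survival(5000, g, log(2), 1e-3, 0, seed = 61)
  fit <- cox_univariate(cl$os_time, cl$os_event, g)
  expect_equal(fit$hazard_ratio, 2, tolerance = 0.05)
})

test_that("resampling screen is reproducible and concordant under effect", {
  set.seed(67)
  g <- rep(0:1, each = 150)
  vals <- rnorm(300, 2 + 3 * g, 0.5)
  cl <- simulate_survival(300, g, log(2), 1e-3, 0.3, seed = 71)
  r1 <- resample_cox(cl$os_time, cl$os_event, vals, reps = 100, seed = 5)
  r2 <- resample_cox(cl$os_time, cl$os_event, vals, reps = 100, seed = 5)
  expect_identical(r1$hr, r2$hr)
  expect_gt(r1$frac_concordant, 0.9)
  expect_gt(r1$median_hr, 1.4)
  expect_false(r1$flagged)
  expect_error(resample_cox(cl$os_time, cl$os_event, vals, frac = 0), "frac")
})

test_that("null resample concordance exceeds one half on average", {
  # 70% subsamples share data with the full fit, so even with no planted
  # effect their hazard-ratio signs correlate with the full fit's sign.
  set.seed(73)
  conc <- replicate(6, {
    n <- 200
    vals <- rnorm(n)
    cl <- simulate_survival(n, rep(0, n), 0, 1e-3, 0.3)
    resample_cox(cl$os_time, cl$os_event, vals, reps = 60)$frac_concordant
  })
  expect_gt(mean(conc), 0.5)
})

test_that("survival screen recovers planted effect signs and flags gaps", {
  sim <- simulate_multicancer(
    simulation_config(n_cancers = 1, n_tumour = 400, n_normal = 0,
                      n_genes = 25, n_program_genes = 10,
                      survival_log_hr = log(2), rng_seed = 79))
  scr <- survival_screen(sim$bundles, c("SFRP2", "ABSENT"), reps = 60, seed = 3)
  hit <- scr[scr$gene == "SFRP2", ]
  expect_gt(hit$hazard_ratio, 1)
  expect_gt(hit$ci_low, 1)
  expect_false(hit$flagged)
  expect_equal(hit$n_high + hit$n_low, hit$n)
  missing <- scr[scr$gene == "ABSENT", ]
  expect_true(missing$flagged)
  expect_match(missing$note, "absent")

  prot <- simulate_multicancer(
    simulation_config(n_cancers = 1, n_tumour = 400, n_normal = 0,
                      n_genes = 25, n_program_genes = 10,
                      survival_log_hr = -log(2), rng_seed = 83))
  scr2 <- survival_screen(prot$bundles, "SFRP2", reps = 60, seed = 3)
  expect_lt(scr2$hazard_ratio, 1)
})
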