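test_that("LOWESS reproduces affine and constant input exactly", {
  x <- 1:40
  y <- 2 * x + 1
  for (f in c(0.2, 2 / 3, 1.0)) {
    sm <- lowess_smooth(x, y, fraction = f)
    expect_lt(max(abs(sm$y_smooth - y)), 1e-10)
  }
  sm <- lowess_smooth(x, rep(3.5, 40))
  expect_lt(max(abs(sm$y_smooth - 3.5)), 1e-10)
})

test_that("LOWESS agrees with a brute-force weighted-least-squares oracle", {
  set.seed(61)
  x <- as.numeric(1:40)
  y <- sin(x / 6) + rnorm(40, 0, 0.1)
  for (f in c(0.25, 0.5)) {
    sm <- lowess_smooth(x, y, fraction = f)
    oracle <- vapply(x, function(xi) oracle_lowess_point(x, y, xi, f), 0)
    expect_equal(sm$y_smooth, oracle, tolerance = 1e-8)
  }
})

test_that("small-span LOWESS recovers each segment of a noiseless kink", {
  x <- 1:40
  y <- 0.1 * pmin(x, 16)
  sm <- lowess_smooth(x, y, fraction = 0.2)
  away <- abs(x - 16) > 3
  expect_lt(max(abs(sm$y_smooth - y)[away]), 0.02)
})

test_that("LOWESS input validation", {
  expect_error(lowess_smooth(1:2, 1:2), "3 distinct")
  expect_error(lowess_smooth(c(1, 3, 2), 1:3), "increasing")
  expect_error(lowess_smooth(1:5, 1:5, fraction = 0), "fraction")
  expect_error(lowess_smooth(1:5, 1:5, fraction = 1.5), "fraction")
})

test_that("chow_f equals the brute-force three-regression oracle", {
  set.seed(71)
  for (rep in 1:50) {
    x <- sort(runif(20, 0, 50))
    y <- 0.2 * x + rnorm(20, 0, 2)
    w <- if (rep %% 2 == 0) runif(20, 0.5, 3) else NULL
    k <- x[sample(4:17, 1)]
    got <- chow_f(x, y, k, weights = w)
    want <- oracle_chow_f(x, y, k,
                          w = if (is.null(w)) rep(1, 20) else w)
    expect_equal(got$f_stat, want$f, tolerance = 1e-8)
    expect_equal(got$rss_pooled, want$rss_pooled, tolerance = 1e-8)
    expect_equal(got$rss_left, want$rss_left, tolerance = 1e-8)
    expect_equal(got$rss_right, want$rss_right, tolerance = 1e-8)
    expect_gte(got$f_stat, 0)
  }
})

test_that("degenerate Chow cases are defined as documented", {
  x <- 1:30
  # one exact line: segmenting cannot improve a zero pooled residual
  line <- 3 - 0.5 * x
  for (k in c(5, 15, 25)) {
    res <- chow_f(x, line, k)
    expect_identical(res$f_stat, 0)
    expect_identical(res$p_value, 1)
  }
  # exact kink: only the split sharing the kink point fits both segments
  # exactly, because the kink lies on both regimes' lines
  kink <- 0.1 * pmin(x, 16)
  res <- chow_f(x, kink, 16)
  expect_identical(res$f_stat, Inf)
  expect_identical(res$p_value, 0)
  expect_true(is.finite(chow_f(x, kink, 15)$f_stat))
  expect_true(is.finite(chow_f(x, kink, 17)$f_stat))
  expect_error(chow_f(x, kink, 2), "undersized")
})

test_that("the scan identifies an exact kink uniquely", {
  x <- 1:40
  bp <- chow_scan(as_curve(x, 0.1 * pmin(x, 16)))
  expect_equal(bp$k_hat, 16)
  expect_identical(bp$f_stat, Inf)
  expect_true(bp$significant)
  cands <- bp$candidates
  expect_identical(cands$k[!is.finite(cands$f_stat)], 16)
  expect_error(chow_scan(as_curve(1:4, rnorm(4))), "candidate")
})

test_that("the scan recovers a noisy kink near its true location", {
  set.seed(83)
  x <- 1:40
  k_hat <- replicate(500, {
    y <- 0.1 * pmin(x, 16) + rnorm(40, 0, 0.15)
    chow_scan(as_curve(x, y))$k_hat
  })
  expect_lte(abs(median(k_hat) - 16), 1)
})

test_that("end-to-end cutpoint recovery and the no-break null", {
  cfg <- eln_generator_config(
    n_patients = 50000, seed = 53, mode = "piecewise",
    piecewise = list(alpha = -1.2, beta1 = 0.08, beta2 = 0, n_star = 16)
  )
  co <- generate_cohort(cfg)
  bp <- find_cutpoint(co)
  expect_lte(abs(bp$k_hat - 16), 2)
  expect_true(bp$significant)
  expect_s3_class(bp$provenance$curve, "eln_ratio_curve")
  expect_equal(bp$provenance$smoothed$fraction, 2 / 3)

  # no planted break: the scan should rarely call one
  sig <- vapply(1:20, function(s) {
    cfg0 <- eln_generator_config(
      n_patients = 20000, seed = s, mode = "piecewise",
      piecewise = list(alpha = -1.2, beta1 = 0.04, beta2 = 0.04,
                       n_star = 16)
    )
    find_cutpoint(generate_cohort(cfg0), alpha = 0.01)$significant
  }, logical(1))
  expect_gte(mean(!sig), 0.9)
})

test_that("a smooth mechanistic saturation localizes at its population knee", {
  # When the bend is a smooth hypergeometric saturation rather than an exact
  # kink, the scan's estimand is the breakpoint of the best two-line fit to
  # the noiseless expected log-odds curve. Compute that population value
  # from the generating mechanism directly, then check the sample scan
  # concentrates on it (soft robustness check).
  mech <- list(basin_mu = 30, basin_size = 10, pos_mu = 3, pos_size = 2)
  prev <- 0.55
  nmax <- 45L
  set.seed(1)
  reps <- 200000
  B <- 1 + rnbinom(reps, mu = mech$basin_mu - 1, size = mech$basin_size)
  M <- pmin(1 + rnbinom(reps, mu = mech$pos_mu - 1, size = mech$pos_size), B)
  expected_log_odds <- vapply(1:nmax, function(n) {
    Bn <- pmax(B, n)
    p_detect <- mean(1 - exp(lchoose(Bn - M, n) - lchoose(Bn, n)))
    qlogis(prev * p_detect)
  }, 0)
  # weight levels by how often the cohort visits them
  g <- c(0.152, 0.218, 0.273, 0.357)
  mus <- c(9.5, 11.5, 14.5, 16); szs <- c(1.8, 1.7, 2.0, 3.2)
  freq <- vapply(1:nmax, function(n) {
    sum(g * dnbinom(n - 1, mu = mus, size = szs))
  }, 0)
  pop_k <- chow_scan(as_curve(1:nmax,
                              expected_log_odds - expected_log_odds[1],
                              weights = freq))$k_hat
  cfg <- eln_generator_config(n_patients = 50000, seed = 59,
                              mode = "mechanistic",
                              true_node_pos_prev = prev,
                              mechanistic = mech)
  bp <- find_cutpoint(generate_cohort(cfg))
  expect_lte(abs(bp$k_hat - pop_k), 3)
})

test_that("the cutpoint is invariant to the order records are supplied", {
  cfg <- eln_generator_config(n_patients = 10000, seed = 67,
                              mode = "piecewise")
  co <- generate_cohort(cfg)
  bp1 <- find_cutpoint(co)
  set.seed(1)
  bp2 <- find_cutpoint(co[sample(nrow(co)), ])
  expect_equal(bp2$k_hat, bp1$k_hat)
  expect_equal(bp2$f_stat, bp1$f_stat, tolerance = 1e-8)
})
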