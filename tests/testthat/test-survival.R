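test_that("the product-limit estimator matches hand computation", {
  co <- toy_cohort(eln = c(5, 5, 5), pos = 0, months = c(1, 2, 3), event = 1)
  km <- km_estimate(co)
  expect_equal(km$steps$time, c(1, 2, 3))
  expect_equal(km$steps$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median_months, 2)
})

test_that("without censoring the KM curve is one minus the empirical CDF", {
  set.seed(41)
  t <- round(rexp(60, 0.05), 1)
  co <- toy_cohort(eln = 5, pos = 0, months = t, event = 1)
  km <- km_estimate(co)
  ecdf_t <- ecdf(t)
  expect_equal(km$steps$surv, 1 - ecdf_t(km$steps$time))
})

test_that("an all-censored group reports survival 1 and no median", {
  co <- toy_cohort(eln = 5, pos = 0, months = c(10, 20, 30), event = 0)
  km <- km_estimate(co)
  expect_true(all(km$steps$surv == 1))
  expect_true(is.na(km$median_months))
  expect_equal(km$survival_at_60mo, 1)
  expect_error(km_estimate(co[0, ]), "empty")
})

test_that("KM at-risk accounting is conserved step by step", {
  set.seed(6)
  co <- toy_cohort(eln = 5, pos = 0, months = round(rexp(200, 0.03)),
                   event = rbinom(200, 1, 0.7))
  km <- km_estimate(co)
  s <- km$steps
  expect_equal(s$n_risk[-1], (s$n_risk - s$n_event - s$n_censor)[-nrow(s)])
})

test_that("log-rank on two identical samples is exactly null", {
  co <- toy_cohort(eln = 5, pos = 0, months = c(3, 6, 9, 12),
                   event = c(1, 1, 0, 1))
  both <- rbind(co, co)
  lr <- logrank_test(both, rep(c("a", "b"), each = 4))
  expect_equal(lr$chi_square, 0)
  expect_equal(lr$p_value, 1)
  expect_equal(lr$df, 1L)
})

test_that("log-rank detects gross separation and rejects degenerate input", {
  set.seed(13)
  co <- toy_cohort(eln = 5, pos = 0,
                   months = c(rexp(200, 0.01), rexp(200, 0.1)), event = 1)
  lr <- logrank_test(co, rep(c("lo", "hi"), each = 200))
  expect_lt(lr$p_value, 0.001)
  expect_error(logrank_test(co, rep("lo", 400)), "two groups")
  cens <- toy_cohort(eln = 5, pos = 0, months = 1:10, event = 0)
  expect_error(logrank_test(cens, rep(c("a", "b"), 5)), "event")
})

test_that("a null covariate gives a Cox interval covering 1", {
  # survival independent of the examined count by construction
  cfg <- eln_generator_config(
    n_patients = 5000, seed = 19, mode = "piecewise",
    true_node_pos_prev = 0.3,
    piecewise = list(alpha = 0, beta1 = 0, beta2 = 0, n_star = 16)
  )
  co <- generate_cohort(cfg)
  fit <- fit_cox_continuous(co, "node-negative", adjust = NULL)
  expect_lt(fit$ci95[1], 1)
  expect_gt(fit$ci95[2], 1)
})

test_that("Cox fits are invariant to rescaling time", {
  co <- generate_cohort(eln_generator_config(n_patients = 2000, seed = 23))
  base <- fit_cox_continuous(co, "node-negative")
  scaled <- co
  scaled$survival_months <- scaled$survival_months * 7.3
  expect_equal(fit_cox_continuous(scaled, "node-negative")$hr_per_eln,
               base$hr_per_eln, tolerance = 1e-8)
})

test_that("the HR curve anchors at 1 and matches the exponential oracle", {
  set.seed(29)
  n <- 4000
  eln <- rep(c(16L, 30L), each = n / 2)
  rate <- ifelse(eln == 16, 0.04, 0.02)
  co <- toy_cohort(eln, pos = 0, months = rexp(n, rate), event = 1)
  curve <- per_count_hr_curve(co, stratum = "all", reference_count = 16,
                              adjust = NULL, min_per_level = 1)
  expect_identical(curve$ratio[curve$level == 16], 1)
  # with exponential times and no censoring the HR is the rate ratio
  emp_ratio <- (sum(eln == 30) / sum(co$survival_months[eln == 30])) /
    (sum(eln == 16) / sum(co$survival_months[eln == 16]))
  expect_equal(curve$ratio[curve$level == 30], emp_ratio, tolerance = 0.05)
})

test_that("beyond-cutoff HR curve is flat when survival ignores the count", {
  cfg <- eln_generator_config(
    n_patients = 50000, seed = 37, mode = "piecewise",
    true_node_pos_prev = 0.3,
    piecewise = list(alpha = 0.5, beta1 = 0, beta2 = 0, n_star = 16)
  )
  co <- generate_cohort(cfg) # prevalence below observed logit => truth = observed
  curve <- per_count_hr_curve(co, stratum = "node-negative",
                              reference_count = 16)
  fit <- lm(log_ratio ~ level, data = as.data.frame(curve),
            weights = ifelse(curve$se > 0, 1 / curve$se^2, 0))
  ci <- confint(fit)["level", ]
  expect_lt(ci[1], 0)
  expect_gt(ci[2], 0)
})

test_that("under-staged patients depress survival below the cutoff", {
  co <- generate_cohort(eln_generator_config(n_patients = 20000, seed = 43))
  cmp <- km_compare_at_cutoff(co, 16, stratum = "node-negative")
  expect_gt(cmp$above$survival_at_60mo, cmp$below$survival_at_60mo)
  expect_error(km_compare_at_cutoff(co, 0), "one-sided")
})

test_that("zero-event strata are refused", {
  co <- toy_cohort(eln = 5:14, pos = 0, months = 1:10, event = 0)
  expect_error(fit_cox_continuous(co, "node-negative"), "zero events")
})
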