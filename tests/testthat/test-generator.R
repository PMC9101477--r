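test_that("identical config and seed reproduce the cohort byte for byte", {
  cfg <- eln_generator_config(n_patients = 500, seed = 42)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_cohort(generate_cohort(cfg), f1)
  write_cohort(generate_cohort(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))

  # the caller's RNG stream is not consumed
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_cohort(cfg))
  expect_identical(runif(1), before)
})

test_that("zero true prevalence yields an all-node-negative cohort", {
  for (mode in c("mechanistic", "piecewise")) {
    co <- generate_cohort(eln_generator_config(n_patients = 300, seed = 1,
                                               mode = mode,
                                               true_node_pos_prev = 0))
    expect_true(all(co$observed_n_stage == "N0"))
    expect_true(all(co$positive_nodes_examined == 0L))
    expect_false(any(co$true_node_positive))
  }
})

test_that("exhaustive nodal sampling observes the true prevalence", {
  prev <- 0.55
  cfg <- eln_generator_config(
    n_patients = 20000, seed = 77, mode = "mechanistic",
    true_node_pos_prev = prev,
    mechanistic = list(examine_all = TRUE)
  )
  co <- generate_cohort(cfg, keep_latent = TRUE)
  # every node in the basin is examined, so detection is certain
  expect_identical(co$positive_nodes_examined > 0, co$true_node_positive)
  expect_true(all(co$undetected_positive_nodes == 0L))
  rate <- mean(co$observed_n_stage != "N0")
  se <- sqrt(prev * (1 - prev) / nrow(co))
  expect_lt(abs(rate - prev), 3 * se)
})

test_that("logistic regression recovers the planted piecewise coefficients", {
  cfg <- eln_generator_config(
    n_patients = 50000, seed = 2024, mode = "piecewise",
    piecewise = list(alpha = -1.2, beta1 = 0.08, beta2 = 0, n_star = 16)
  )
  co <- generate_cohort(cfg)
  y <- as.integer(co$observed_n_stage != "N0")
  x1 <- pmin(co$eln_count, 16)
  x2 <- pmax(0, co$eln_count - 16)
  fit <- glm(y ~ x1 + x2, family = binomial())
  est <- summary(fit)$coefficients
  ci1 <- est["x1", "Estimate"] + c(-1, 1) * 1.96 * est["x1", "Std. Error"]
  ci2 <- est["x2", "Estimate"] + c(-1, 1) * 1.96 * est["x2", "Std. Error"]
  expect_gt(0.08, ci1[1]); expect_lt(0.08, ci1[2])
  expect_gt(0.00, ci2[1]); expect_lt(0.00, ci2[2])
})

test_that("record-level invariants hold in both modes", {
  for (mode in c("mechanistic", "piecewise")) {
    co <- generate_cohort(eln_generator_config(n_patients = 5000, seed = 5,
                                               mode = mode),
                          keep_latent = TRUE)
    expect_true(all(co$eln_count >= 1L))
    expect_true(all(co$positive_nodes_examined <= co$eln_count))
    expect_true(all(co$positive_nodes_examined >= 0L))
    # examined positives cannot exceed the positives that exist
    expect_true(all(co$positive_nodes_examined <= co$true_positive_nodes |
                      !co$true_node_positive))
    # a positive node seen implies true disease
    expect_true(all(co$true_node_positive[co$positive_nodes_examined > 0]))
    # AJCC-7 binning: N0 exactly when nothing positive was examined
    expect_identical(co$observed_n_stage == "N0",
                     co$positive_nodes_examined == 0L)
    expect_true(all(co$survival_months >= 0))
  }
})

test_that("mechanistic detection is monotone in the examined count", {
  co <- generate_cohort(eln_generator_config(n_patients = 20000, seed = 12,
                                             mode = "mechanistic"))
  dec <- cut(co$eln_count, quantile(co$eln_count, 0:10 / 10),
             include.lowest = TRUE)
  rate <- tapply(co$observed_n_stage != "N0", dec, mean)
  iso <- isoreg(seq_along(rate), rate)
  expect_lt(max(abs(iso$yf - rate)), 0.03)
  expect_gt(rate[length(rate)], rate[1])
})

test_that("without censoring every record is a death event", {
  cfg <- eln_generator_config(
    n_patients = 1000, seed = 3,
    survival = list(censor_rate = 0, admin_censor_months = Inf)
  )
  co <- generate_cohort(cfg)
  expect_true(all(co$death_event == 1L))
})

test_that("cohort summary reports order statistics and exact partitions", {
  co <- toy_cohort(eln = c(7, 12, 19), pos = c(0, 1, 3),
                   months = c(10, 20, 30), event = c(1, 1, 0))
  s <- summarize_cohort(co)
  expect_equal(unname(s$eln_overall["median"]), 12)
  expect_equal(unname(s$eln_overall["q25"]), 7)
  expect_equal(unname(s$eln_overall["q75"]), 19)

  co2 <- generate_cohort(eln_generator_config(n_patients = 2000, seed = 8))
  s2 <- summarize_cohort(co2)
  expect_equal(sum(s2$by_n_stage), nrow(co2))
  expect_equal(sum(s2$by_year_group), nrow(co2))
  expect_error(summarize_cohort(co2[0, ]), "empty")
})

test_that("invalid generator configurations are rejected", {
  expect_error(eln_generator_config(year_group_weights = c(0.5, 0.6)),
               "probability")
  expect_error(eln_generator_config(t_stage_probs = c(T0 = -0.1, T1 = 1.1)),
               "probability")
  expect_error(eln_generator_config(mode = "piecewise",
                                    piecewise = list(n_star = 1)),
               "n_star")
  expect_error(eln_generator_config(mode = "piecewise",
                                    piecewise = list(n_star = 5000)),
               "support")
  expect_error(eln_generator_config(survival = list(baseline_hazard = 0)),
               "baseline_hazard")
})
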