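test_that("simulate_arm honours the censoring mechanism and is deterministic", {
  m <- true_arm_model("exponential", c(rate = 0.1), "a")
  d <- simulate_arm(m, censoring_spec(1e6, 0), 100, seed = 7)
  expect_equal(nrow(d), 100)
  expect_true(all(d$event == 1))
  expect_true(all(d$time > 0))

  d2 <- simulate_arm(m, censoring_spec(1e6, 0), 100, seed = 7)
  expect_identical(d, d2)

  # Monte-Carlo against the closed-form mean 1/rate
  big <- simulate_arm(m, censoring_spec(1e9, 0), 10000, seed = 1)
  expect_lt(abs(mean(big$time) - 10) / 10, 0.05)

  # censored records are cut at the administrative time
  dc <- simulate_arm(m, censoring_spec(5, 0), 1000, seed = 2)
  expect_true(all(dc$time <= 5))
  expect_true(all(dc$time[dc$event == 0] == 5))
})

test_that("invalid generator inputs are rejected", {
  expect_error(true_arm_model("weibull", c(shape = -1, scale = 2)),
               class = "partsurv_parameter_error")
  expect_error(true_arm_model("notafamily", c(rate = 1)),
               class = "partsurv_parameter_error")
  expect_error(censoring_spec(-1), class = "partsurv_parameter_error")
  m <- true_arm_model("exponential", c(rate = 0.1), "a")
  expect_error(simulate_arm(m, censoring_spec(1, 0), 0, seed = 1),
               class = "partsurv_parameter_error")
})

test_that("empirical KM of a large simulated arm tracks the true survival", {
  m <- true_arm_model("weibull", c(shape = 1.3, scale = 2), "a")
  d <- simulate_arm(m, censoring_spec(3, 0.05), 10000, seed = 5)
  km <- km_estimate(d)
  grid <- seq(0.01, 3, length.out = 300)
  truth <- partsurv:::family_survival_at("weibull", c(shape = 1.3, scale = 2),
                                         grid)
  expect_lt(max(abs(eval_step(km$step, grid) - truth)), 0.02)
})

test_that("linked endpoints couple PFS below OS per subject", {
  os <- true_arm_model("exponential", c(rate = 0.1), "a")
  pfs <- true_arm_model("exponential", c(rate = 0.3), "a")
  cens <- censoring_spec(20, 0.02)
  pair <- simulate_linked_endpoints(os, pfs, cens, 50, seed = 9)
  expect_true(all(pair$pfs$time <= pair$os$time + 1e-12))

  # marginals that cross are a consistency error
  bad_pfs <- true_arm_model("exponential", c(rate = 0.05), "a")
  expect_error(simulate_linked_endpoints(os, bad_pfs, cens, 50, seed = 9),
               class = "partsurv_consistency_error")

  # empirical ordering of the two KM curves
  big <- simulate_linked_endpoints(os, pfs, censoring_spec(20, 0), 5000,
                                   seed = 10)
  km_os <- km_estimate(big$os)
  km_pfs <- km_estimate(big$pfs)
  expect_lt(eval_step(km_pfs$step, 2), eval_step(km_os$step, 2))
})

test_that("digitize reproduces hand-computed coordinates and risk table", {
  d <- sdat(c(1, 2), c(1, 1))
  dc <- digitize(d, grid_points = 201, risk_table_interval = 0.5)
  i1 <- which(abs(dc$coords$time - 1) < 1e-9)
  i2 <- which(abs(dc$coords$time - 2) < 1e-9)
  expect_equal(dc$coords$surv[i1], 0.5)
  expect_equal(dc$coords$surv[i2], 0)
  expect_equal(dc$total_events, 2)

  # risk interval beyond follow-up: only the t=0 entry remains
  dc2 <- digitize(d, grid_points = 50, risk_table_interval = 10)
  expect_equal(nrow(dc2$risk_table), 1)
  expect_equal(dc2$risk_table$n_risk, 2)

  expect_error(digitize(d, grid_points = 1, risk_table_interval = 1),
               class = "partsurv_parameter_error")
})

test_that("digitisation jitter is repaired to a valid survival function", {
  d <- weibull_arm(n = 200, seed = 4)
  dc <- digitize(d, grid_points = 80, risk_table_interval = 0.5,
                 jitter = 0.02, seed = 8)
  expect_true(all(diff(dc$coords$surv) <= 1e-12))
  expect_equal(dc$coords$surv[1], 1)
  expect_true(all(dc$coords$surv >= 0 & dc$coords$surv <= 1))
})

test_that("the reference scenario validates, runs forward and is reproducible", {
  ref <- make_reference_scenario(seed = 2, n_per_arm = 120)
  expect_s3_class(ref$config, "pipeline_config")
  expect_true(all(ref$datasets$intervention$pfs$time <=
                    ref$datasets$intervention$os$time + 1e-12))
  ref2 <- make_reference_scenario(seed = 2, n_per_arm = 120)
  expect_identical(ref$datasets, ref2$datasets)
  # intervention OS lies above comparator OS at the median-ish time (HR < 1)
  km_i <- km_estimate(ref$datasets$intervention$os)
  km_c <- km_estimate(ref$datasets$comparator$os)
  expect_gt(eval_step(km_i$step, 1.5), eval_step(km_c$step, 1.5))
})
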