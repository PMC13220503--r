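exp_fn <- function(rate) surv_fn_family("exponential", c(rate = rate))

test_that("occupancy is read off the curves with conservation and clipping", {
  s <- exp_fn(0.2)
  spec <- partsa_spec(s, s, cycle_length = 1 / 52, horizon = 40)
  tr <- build_traces(spec)
  expect_true(all(abs(tr$pf + tr$pd + tr$dead - 1) <= 1e-9))
  expect_true(all(tr$pd == 0))            # identical curves: no progressed state
  expect_true(all(diff(tr$dead) >= -1e-12))

  # constructed PFS above OS on an interval: clipped, conservation preserved
  pfs_high <- surv_fn(function(t) pmin(1, exp(-0.2 * t) + 0.05))
  spec2 <- partsa_spec(exp_fn(0.2), pfs_high, cycle_length = 1 / 26,
                       horizon = 20)
  tr2 <- build_traces(spec2)
  expect_gt(attr(tr2, "n_clipped"), 0)
  expect_true(all(abs(tr2$pf + tr2$pd + tr2$dead - 1) <= 1e-9))
  expect_true(all(tr2$pf <= 1 - tr2$dead + 1e-12))
})

test_that("weekly-cycle life-years match the closed form and the quadrature oracle", {
  spec <- partsa_spec(exp_fn(0.2), exp_fn(0.4), cycle_length = 1 / 52,
                      horizon = 40, discount_qaly = 0)
  tr <- build_traces(spec)
  u <- utility_spec(1, 1)
  acc <- accumulate_qalys(tr, u, discount_rate = 0)
  closed <- (1 - exp(-8)) / 0.2
  expect_lt(abs(acc$ly - closed) / closed, 0.005)
  expect_equal(acc$qalys, acc$ly)  # utility 1 and no decrement: QALYs == LY

  # discounted case against the adaptive-quadrature oracle
  acc_d <- accumulate_qalys(tr, utility_spec(0.77, 0.77), 0.035)
  oracle <- 0.77 * restricted_mean(exp_fn(0.2), 40, 0.035)
  expect_lt(abs(acc_d$qalys - oracle) / oracle, 0.005)
  expect_lte(acc_d$qalys, acc$qalys)  # discounted <= undiscounted
})

test_that("cycle-length refinement converges", {
  ly_at <- function(h) {
    spec <- partsa_spec(exp_fn(0.15), exp_fn(0.3), cycle_length = h,
                        horizon = 40)
    accumulate_qalys(build_traces(spec), utility_spec(1, 1), 0)$ly
  }
  expect_lt(abs(ly_at(1 / 104) - ly_at(1 / 52)) / ly_at(1 / 52), 0.002)
})

test_that("treatment exposure follows TTD curves and fixed durations", {
  spec <- partsa_spec(exp_fn(0.1), exp_fn(0.3), ttd = 0.5,
                      cycle_length = 1 / 52, horizon = 10)
  tr <- build_traces(spec)
  expect_true(all(tr$on_trt[tr$time < 0.5] == tr$pf[tr$time < 0.5]))
  expect_true(all(tr$on_trt[tr$time >= 0.5] == 0))

  ttd_fn <- exp_fn(1.5)
  spec2 <- partsa_spec(exp_fn(0.1), exp_fn(0.3), ttd = ttd_fn,
                       cycle_length = 1 / 52, horizon = 10)
  tr2 <- build_traces(spec2)
  expect_true(all(tr2$on_trt <= tr2$pf + 1e-12))
  expect_true(all(tr2$on_trt <= eval_surv(ttd_fn, tr2$time) + 1e-12))
})

test_that("terminal cost conserves to the unit cost under full mortality", {
  # survival reaching exactly 0 inside the horizon, undiscounted
  lin <- surv_fn(function(t) pmax(1 - t / 10, 0))
  spec <- partsa_spec(lin, lin, cycle_length = 1 / 52, horizon = 20,
                      discount_cost = 0)
  tr <- build_traces(spec)
  costs <- arm_cost_spec(terminal = 6265)
  out <- accumulate_costs(tr, costs, discount_rate = 0)
  expect_equal(out$terminal, 6265)
  expect_equal(out$total, 6265)
})

test_that("state costs are occupancy-months times the monthly rates", {
  lin <- surv_fn(function(t) pmax(1 - t / 10, 0))
  spec <- partsa_spec(lin, lin, cycle_length = 1 / 52, horizon = 20,
                      discount_cost = 0)
  tr <- build_traces(spec)
  # PD occupancy is identically zero, so only PF-months accrue at 133/month
  out <- accumulate_costs(tr, arm_cost_spec(state_pf_monthly = 133,
                                            state_pd_monthly = 273),
                          discount_rate = 0)
  pf_years <- 10 / 2  # area under the linear survival
  expect_equal(out$state, 133 * 12 * pf_years, tolerance = 1e-9)
})

test_that("accumulators are exactly linear in unit costs and utilities", {
  spec <- partsa_spec(exp_fn(0.2), exp_fn(0.5), ttd = 0.4,
                      cycle_length = 1 / 52, horizon = 30)
  tr <- build_traces(spec)
  base <- arm_cost_spec(acquisition_weekly = 100, admin_monthly = 819,
                        state_pf_monthly = 133, state_pd_monthly = 273,
                        terminal = 6265, ae_cost = 300)
  doubled <- arm_cost_spec(acquisition_weekly = 200, admin_monthly = 1638,
                           state_pf_monthly = 266, state_pd_monthly = 546,
                           terminal = 12530, ae_cost = 600)
  c1 <- accumulate_costs(tr, base, 0.035)
  c2 <- accumulate_costs(tr, doubled, 0.035)
  expect_equal(c2$total, 2 * c1$total, tolerance = 1e-12)

  q1 <- accumulate_qalys(tr, utility_spec(0.4, 0.3), 0.035)
  q2 <- accumulate_qalys(tr, utility_spec(0.8, 0.6), 0.035)
  expect_equal(q2$qalys, 2 * q1$qalys, tolerance = 1e-12)
})

test_that("identical arms yield exactly zero increments", {
  spec <- partsa_spec(exp_fn(0.2), exp_fn(0.5), ttd = 0.4,
                      cycle_length = 1 / 26, horizon = 30)
  u <- utility_spec(0.77, 0.68)
  costs <- arm_cost_spec(acquisition_weekly = 50, admin_monthly = 819,
                         state_pf_monthly = 133, state_pd_monthly = 273,
                         terminal = 6265)
  cmp <- run_comparison(spec, spec, u, costs, costs)
  expect_identical(cmp$d_ly, 0)
  expect_identical(cmp$d_qalys, 0)
  expect_identical(cmp$d_cost, 0)

  # near-identical arms: increments shrink continuously
  spec_eps <- partsa_spec(apply_hazard_ratio(exp_fn(0.2), 0.999),
                          apply_hazard_ratio(exp_fn(0.5), 0.999),
                          ttd = 0.4, cycle_length = 1 / 26, horizon = 30)
  cmp_eps <- run_comparison(spec_eps, spec, u, costs, costs)
  expect_lt(abs(cmp_eps$d_qalys), 0.01)
  expect_gt(cmp_eps$d_qalys, 0)
})

test_that("mismatched cycle structures are a configuration error", {
  a <- partsa_spec(exp_fn(0.2), exp_fn(0.5), cycle_length = 1 / 52,
                   horizon = 30)
  b <- partsa_spec(exp_fn(0.2), exp_fn(0.5), cycle_length = 1 / 26,
                   horizon = 30)
  expect_error(run_comparison(a, b, utility_spec(0.77, 0.68),
                              arm_cost_spec(), arm_cost_spec()),
               class = "partsurv_config_error")
})

test_that("age decrement reduces QALYs but never life-years", {
  spec <- partsa_spec(exp_fn(0.1), exp_fn(0.2), cycle_length = 1 / 52,
                      horizon = 40)
  tr <- build_traces(spec)
  q0 <- accumulate_qalys(tr, utility_spec(0.77, 0.68, 0), 0.035)
  q1 <- accumulate_qalys(tr, utility_spec(0.77, 0.68, 0.003), 0.035)
  expect_lt(q1$qalys, q0$qalys)
  expect_equal(q1$ly, q0$ly)
})
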