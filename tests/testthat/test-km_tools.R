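test_that("km_estimate matches hand-computed product limits", {
  km <- km_estimate(sdat(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(eval_step(km$step, c(1, 2, 3)), c(2, 1, 0) / 3)

  # censoring between events: (4/5)(3/4)(1/2) = 0.3
  km2 <- km_estimate(sdat(c(1, 2, 2.5, 3, 4), c(1, 1, 0, 1, 0)))
  expect_equal(eval_step(km2$step, 3), 0.3)

  # all censored: flat at 1
  km3 <- km_estimate(sdat(c(1, 2, 3), c(0, 0, 0)))
  expect_equal(eval_step(km3$step, c(0.5, 2, 10)), c(1, 1, 1))

  # Greenwood standard errors present and zero drops have none
  expect_true(all(c("std_err", "n_risk") %in% names(km$table)))
})

test_that("reconstruct_ipd inverts clean single-interval curves exactly", {
  dc <- digitized_curve(data.frame(time = c(0, 1), surv = c(1, 0.5)),
                        data.frame(time = c(0, 1), n_risk = c(10, 5)))
  rec <- reconstruct_ipd(dc)
  expect_equal(sum(rec$event == 1 & rec$time == 1), 5)
  expect_equal(sum(rec$event == 0 & rec$time < 1), 0)
  expect_equal(nrow(rec), 10)

  # flat curve: no drops means everyone censored
  dc2 <- digitized_curve(data.frame(time = c(0, 2), surv = c(1, 1)),
                         data.frame(time = c(0, 2), n_risk = c(10, 4)))
  rec2 <- reconstruct_ipd(dc2)
  expect_equal(sum(rec2$event), 0)
  expect_equal(sum(rec2$time <= 2 & rec2$event == 0), 10)
  expect_equal(sum(rec2$time < 2), 6)  # six censored inside (0, 2)
})

test_that("infeasible risk tables raise a reconstruction error naming the interval", {
  dc <- digitized_curve(data.frame(time = c(0, 0.5, 1), surv = c(1, 0.2, 0.2)),
                        data.frame(time = c(0, 1), n_risk = c(10, 8)))
  err <- expect_error(reconstruct_ipd(dc),
                      class = "partsurv_reconstruction_error")
  expect_match(conditionMessage(err), "interval 1")
})

test_that("digitize -> reconstruct round trip preserves the evidence", {
  d <- weibull_arm(n = 300, seed = 11)
  km <- km_estimate(d)

  # fidelity to the digitised curve at a publication-like 60-point grid
  dc <- digitize(d, grid_points = 60, risk_table_interval = 0.5)
  rec <- reconstruct_ipd(dc)
  km_rec <- km_estimate(rec)
  expect_lt(max(abs(eval_step(km_rec$step, dc$coords$time) - dc$coords$surv)),
            0.02)
  expect_lt(abs(sum(rec$event) - sum(d$event)) / sum(d$event), 0.05)
  expect_equal(nrow(rec), nrow(d))

  # agreement with the original data's KM at a fine grid
  dcf <- digitize(d, grid_points = 250, risk_table_interval = 0.5)
  recf <- reconstruct_ipd(dcf)
  kmf <- km_estimate(recf)
  grid <- seq(0, max(d$time), length.out = 1500)
  expect_lt(max(abs(eval_step(km$step, grid) - eval_step(kmf$step, grid))),
            0.02)

  # the no-total-events variant still reconstructs closely
  dc_na <- digitized_curve(dc$coords, dc$risk_table, total_events = NULL)
  rec_na <- reconstruct_ipd(dc_na)
  km_na <- km_estimate(rec_na)
  expect_lt(max(abs(eval_step(km_na$step, dc$coords$time) - dc$coords$surv)),
            0.03)
})

test_that("piecewise hazard is definitional and consistent under bin merging", {
  # 2 events in [0,1): person-time 0.5 + 0.8 + 4 * 1 = 5.3? use explicit data
  d <- sdat(c(0.5, 0.8, rep(2, 4)), c(1, 1, rep(0, 4)))
  ph <- piecewise_hazard(d, bin_width = 1)
  pt_bin1 <- 0.5 + 0.8 + 4
  expect_equal(ph$hazard[1], 2 / pt_bin1)

  # no events anywhere: hazard identically zero
  ph0 <- piecewise_hazard(sdat(c(1, 2, 3), c(0, 0, 0)), bin_width = 1)
  expect_true(all(ph0$hazard == 0))

  # constant-hazard recovery on a large sample
  d2 <- simulate_arm(true_arm_model("exponential", c(rate = 0.1), "a"),
                     censoring_spec(1000, 0), 5000, seed = 5)
  ph2 <- piecewise_hazard(d2, bin_width = 1)
  early <- ph2[ph2$time < 10, ]
  expect_true(all(abs(early$hazard - 0.1) / 0.1 < 0.2))

  # merged bins equal the person-time-weighted average of sub-bins
  wide <- piecewise_hazard(d2, bin_width = 2)
  narrow <- piecewise_hazard(d2, bin_width = 1)
  h_merged <- wide$hazard[1]
  w <- narrow$person_time[1:2]
  expect_equal(h_merged, sum(narrow$hazard[1:2] * w) / sum(w))
})

test_that("smoothed hazard is non-negative and tracks known shapes", {
  d <- simulate_arm(true_arm_model("exponential", c(rate = 0.2), "a"),
                    censoring_spec(30, 0), 5000, seed = 3)
  sh <- smoothed_hazard(d)
  expect_true(all(sh$hazard >= 0))
  interior <- sh$time > quantile(d$time, 0.1) & sh$time < quantile(d$time, 0.9)
  expect_true(all(sh$hazard[interior] > 0.15 & sh$hazard[interior] < 0.25))

  # integrated smoothed hazard close to the Nelson-Aalen cumulative total
  na_total <- sum(d$event / vapply(d$time, function(t) sum(d$time >= t),
                                   numeric(1)))
  fine <- smoothed_hazard(d, n_grid = 400)
  ih <- sum(fine$hazard) * diff(fine$time[1:2])
  expect_lt(abs(ih - na_total) / na_total, 0.15)

  # increasing-hazard data: later hazard exceeds earlier hazard
  dw <- simulate_arm(true_arm_model("weibull", c(shape = 2, scale = 5), "a"),
                     censoring_spec(30, 0), 3000, seed = 4)
  shw <- smoothed_hazard(dw)
  q <- quantile(dw$time, c(0.25, 0.75))
  h25 <- shw$hazard[which.min(abs(shw$time - q[1]))]
  h75 <- shw$hazard[which.min(abs(shw$time - q[2]))]
  expect_gt(h75, h25)

  expect_error(smoothed_hazard(sdat(c(1, 2, 3), c(1, 1, 1))),
               class = "partsurv_estimation_error")
})
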