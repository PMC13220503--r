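test_that("weighted tender prices follow the share-weighted mean and median", {
  tp <- data.frame(price = c(100, 80), share = c(0.25, 0.75))
  expect_equal(weighted_price(tp, "mean"), 85)
  expect_equal(weighted_price(tp, "median"), 80)

  single <- data.frame(price = 123, share = 1)
  expect_equal(weighted_price(single, "mean"), 123)
  expect_equal(weighted_price(single, "median"), 123)

  expect_error(weighted_price(data.frame(price = c(1, 2),
                                         share = c(0.5, 0.4))),
               class = "partsurv_config_error")

  # merging two tenders with equal prices leaves the weighted mean unchanged
  merged <- data.frame(price = c(100, 80), share = c(0.25, 0.75))
  split3 <- data.frame(price = c(100, 80, 80), share = c(0.25, 0.40, 0.35))
  expect_equal(weighted_price(split3, "mean"), weighted_price(merged, "mean"))
})

test_that("the worked vial example prices at 180 without sharing, 157.50 with", {
  vials <- data.frame(size = c(100, 400), price = c(50, 180))
  # 70 kg x 5 mg/kg x RDI 1 = 350 mg
  bodies <- body_metric_distribution(
    weight = list(male = rep(70, 5), female = rep(70, 5)), prop_female = 0.4)
  no_share <- expected_vial_cost(list(type = "per_kg", dose = 5), bodies,
                                 rdi = 1, vial_options = vials,
                                 sharing = FALSE)
  expect_equal(no_share$expected_cost, 180)
  share <- expected_vial_cost(list(type = "per_kg", dose = 5), bodies,
                              rdi = 1, vial_options = vials, sharing = TRUE)
  expect_equal(share$expected_cost, 350 * 180 / 400)
})

test_that("the DP combination is cost-minimal against brute-force enumeration", {
  set.seed(42)  # randomised cases for the oracle comparison only
  for (i in 1:100) {
    n_sizes <- sample(1:3, 1)
    vials <- data.frame(size = sample(c(50, 100, 150, 200, 400), n_sizes),
                        price = round(runif(n_sizes, 20, 300), 2))
    mg <- runif(1, 10, 900)
    dp <- cheapest_vial_combo(mg, vials)
    expect_equal(dp$cost, brute_force_vial_cost(mg, vials),
                 tolerance = 1e-9)
  }
})

test_that("sharing never costs more, and no-sharing cost is a step function of dose", {
  vials <- data.frame(size = c(100, 400), price = c(50, 180))
  per_mg <- min(vials$price / vials$size)
  mgs <- seq(10, 800, by = 10)
  costs <- vapply(mgs, function(m) cheapest_vial_combo(m, vials)$cost,
                  numeric(1))
  expect_true(all(mgs * per_mg <= costs + 1e-9))
  expect_true(all(diff(costs) >= 0))          # non-decreasing in required mg
  expect_lt(length(unique(costs)), length(costs))  # genuinely step-like
})

test_that("dose rules respond to RDI and ignore body metrics when flat", {
  vials <- data.frame(size = 10, price = 7)
  bodies <- body_metric_distribution(
    weight = list(male = c(log(80), 0.15), female = c(log(65), 0.15)),
    prop_female = 0.5)
  full <- expected_vial_cost(list(type = "per_kg", dose = 2), bodies, 1,
                             vials, sharing = TRUE)
  half <- expected_vial_cost(list(type = "per_kg", dose = 2), bodies, 0.5,
                             vials, sharing = TRUE)
  expect_equal(half$expected_cost, full$expected_cost / 2)

  flat_a <- expected_vial_cost(list(type = "flat", dose = 100), bodies, 1,
                               vials, sharing = FALSE)
  flat_b <- expected_vial_cost(list(type = "flat", dose = 100),
                               bodies = NULL, 1, vials, sharing = FALSE)
  expect_equal(flat_a$expected_cost, flat_b$expected_cost)

  expect_error(expected_vial_cost(list(type = "flat", dose = 100), NULL, 1,
                                  vial_options = vials[0, ]),
               class = "partsurv_config_error")
})

test_that("regimen cycle costs prorate administration correctly", {
  bodies <- body_metric_distribution(
    weight = list(male = c(log(78), 0.18), female = c(log(66), 0.19)),
    prop_female = 0.4)
  reg <- list(regimen_component("flat_drug", "flat", 100, interval_weeks = 2,
                                vial_options = data.frame(size = 100,
                                                          price = 40)))
  out <- regimen_cycle_cost(reg, bodies, sharing = FALSE,
                            cycle_length = 1 / 52, admin_monthly = 819)
  # 819/month at one-week cycles -> 819 * 12 / 52 per cycle
  expect_equal(out$admin_per_cycle, 819 * 12 / 52)
  # one administration every 2 weeks -> half a vial-set per weekly cycle
  expect_equal(out$acquisition_per_cycle, 40 / 2)
})

test_that("the body-metric quantile grid is deterministic and weighted by sex", {
  b1 <- body_metric_distribution(
    weight = list(male = c(log(78), 0.18), female = c(log(66), 0.19)),
    prop_female = 0.4)
  b2 <- body_metric_distribution(
    weight = list(male = c(log(78), 0.18), female = c(log(66), 0.19)),
    prop_female = 0.4)
  expect_identical(b1$draw("weight"), b2$draw("weight"))
  g <- b1$draw("weight")
  expect_equal(sum(g$weight), 1, tolerance = 1e-12)
  expect_true(all(g$value > 0))
})
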