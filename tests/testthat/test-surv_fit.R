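test_that("exponential MLE equals events over person-time, with exact AIC/BIC", {
  # 10 events, total person-time 100 years -> rate 0.10
  d <- sdat(rep(10, 10), rep(1, 10))
  fit <- fit_parametric(d, "exponential")
  expect_equal(unname(fit$params["rate"]), 0.10, tolerance = 1e-6)
  expect_equal(fit$aic, 2 - 2 * fit$loglik)
  expect_equal(fit$bic, log(10) - 2 * fit$loglik)

  # mixed censoring: 3 events, person-time 30 -> 0.1
  d2 <- sdat(c(5, 10, 6, 4, 5), c(1, 1, 1, 0, 0))
  fit2 <- fit_parametric(d2, "exponential")
  expect_equal(unname(fit2$params["rate"]), 3 / 30, tolerance = 1e-6)

  expect_error(fit_parametric(sdat(c(1, 2), c(0, 0)), "exponential"),
               class = "partsurv_estimation_error")
})

test_that("weibull parameters are recovered from censored data", {
  d <- simulate_recovery_arm("weibull")
  fit <- fit_parametric(d, "weibull")
  truth <- recovery_cases()$weibull
  expect_true(all(abs(fit$params - truth) / truth < 0.10))
  # covariance is positive semi-definite on the estimation scale
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
})

test_that("fitting is deterministic given the data", {
  d <- weibull_arm(n = 200, seed = 9)
  f1 <- fit_parametric(d, "gengamma")
  f2 <- fit_parametric(d, "gengamma")
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("generalised gamma nests weibull, log-normal and gamma", {
  for (fam in c("weibull", "lognormal", "gamma")) {
    truth <- recovery_cases()[[fam]]
    improvements <- vapply(1:5, function(r) {
      d <- simulate_arm(true_arm_model(fam, truth, "a"),
                        censoring_spec(1e6, 0), 500,
                        seed = 20 + 10 * r + match(fam, surv_families()))
      sub <- fit_parametric(d, fam)
      gg <- fit_parametric(d, "gengamma")
      gg$loglik - sub$loglik
    }, numeric(1))
    # nesting: the 3-parameter fit can never be worse than its sub-model
    expect_true(all(improvements > -1e-4), label = paste(fam, "nesting"))
    # under the sub-model truth the improvement is ~chi-square(1)/2
    # (median 0.23), so the median over replicates sits well below 1.92
    expect_lt(median(improvements), 1.92)
  }
})

test_that("hazard shapes are classified from the analytic hazard", {
  pm <- function(f, p) structure(list(family = f, params = p, converged = TRUE),
                                 class = "parametric_model")
  expect_equal(classify_hazard_shape(pm("exponential", c(rate = 0.1)), 40),
               "constant")
  expect_equal(classify_hazard_shape(pm("weibull", c(shape = 2, scale = 5)), 40),
               "increasing")
  expect_equal(classify_hazard_shape(pm("weibull", c(shape = 0.7, scale = 5)), 40),
               "decreasing")
  expect_equal(classify_hazard_shape(pm("gompertz", c(shape = 0.3, rate = 0.1)), 40),
               "increasing")
  expect_equal(classify_hazard_shape(pm("gompertz", c(shape = -0.3, rate = 0.1)), 40),
               "decreasing")
  expect_equal(classify_hazard_shape(pm("lognormal", c(meanlog = 1, sdlog = 0.5)), 40),
               "unimodal")
})

test_that("fit_all ranks all seven families and respects nesting asymptotics", {
  d <- simulate_recovery_arm("exponential", n = 800)
  rank <- fit_all(d, horizon = 40, preferred_shape = NULL)
  expect_equal(nrow(rank$table), 7)
  expect_true(all(c("converged", "aic", "bic", "hazard_shape") %in%
                    names(rank$table)))
  expect_false(rank$sensitivity_family == rank$base_family)
  # weibull nests exponential: its AIC can exceed the exponential's by at
  # most 2 (one extra parameter), up to optimiser slack
  aic_exp <- rank$table$aic[rank$table$family == "exponential"]
  aic_wei <- rank$table$aic[rank$table$family == "weibull"]
  expect_lt(aic_wei - aic_exp, 2.5)
})

test_that("joint selection picks one family for both arms", {
  d1 <- simulate_recovery_arm("weibull")
  d2 <- simulate_arm(true_arm_model("weibull", c(shape = 1.3, scale = 10), "b"),
                     censoring_spec(12, 0), 800, seed = 31)
  fits <- lapply(list(d1, d2), function(d)
    lapply(setNames(nm = surv_families()), function(f) fit_parametric(d, f)))
  sel <- select_families(fits, horizon = 40, preferred_shape = "increasing")
  expect_true(sel$base %in% surv_families())
  expect_false(identical(sel$base, sel$sensitivity))
  # the chosen family has an increasing-hazard tag in both arms
  for (arm in fits)
    expect_equal(classify_hazard_shape(arm[[sel$base]], 40), "increasing")
})

test_that("proportional-hazards transform behaves as S^hr", {
  base <- surv_fn_family("exponential", c(rate = 0.1))
  expect_equal(eval_surv(apply_hazard_ratio(base, 1), c(1, 5, 20)),
               eval_surv(base, c(1, 5, 20)))
  half <- apply_hazard_ratio(base, 0.5)
  # median of an exp(0.05): log(2)/0.05
  tmed <- log(2) / 0.05
  expect_equal(eval_surv(half, tmed), 0.5, tolerance = 1e-9)
  # monotone in hr
  grid <- c(0.5, 2, 10)
  expect_true(all(eval_surv(apply_hazard_ratio(base, 0.7), grid) >
                    eval_surv(base, grid)))
  expect_true(all(eval_surv(apply_hazard_ratio(base, 1.3), grid) <
                    eval_surv(base, grid)))
  expect_error(apply_hazard_ratio(base, 0), class = "partsurv_parameter_error")
  # published second-line meta-analysis HRs are valid scenario parameters
  expect_s3_class(apply_hazard_ratio(base, 0.75), "surv_fn")
  expect_s3_class(apply_hazard_ratio(base, 0.61), "surv_fn")
})

test_that("restricted mean matches closed forms and monotonicity", {
  s <- surv_fn_family("exponential", c(rate = 0.2))
  expect_equal(restricted_mean(s, 40, 0), (1 - exp(-8)) / 0.2,
               tolerance = 1e-6)
  expect_equal(restricted_mean(s, 1000, 0.035), 1 / (0.2 + log(1.035)),
               tolerance = 1e-6)
  expect_lt(restricted_mean(s, 40, 0.035), restricted_mean(s, 40, 0))
})
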