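# shared fixtures: all data built in code at test time

# a mid-sized weibull arm resembling a first-line oncology OS curve
weibull_arm <- function(n = 300, seed = 11, shape = 1.3, scale = 2,
                        admin = 2.6, dropout = 0.08) {
  simulate_arm(true_arm_model("weibull", c(shape = shape, scale = scale), "a"),
               censoring_spec(admin, dropout), n, seed = seed)
}

# frozen study conditions for own-family parameter recovery: true values
# chosen for identifiability (every parameter estimable with relative SE well
# under the test tolerance at n = 1000); administrative censoring at the 75th
# percentile gives ~25% censored; seed = family index
recovery_cases <- function() {
  list(
    exponential = c(rate = 0.15),
    weibull     = c(shape = 1.3, scale = 8),
    gompertz    = c(shape = 0.8, rate = 0.3),
    lognormal   = c(meanlog = 2, sdlog = 0.5),
    loglogistic = c(shape = 2.2, scale = 7),
    gamma       = c(shape = 3, rate = 0.5),
    gengamma    = c(mu = 2, sigma = 0.6, Q = -2)
  )
}

simulate_recovery_arm <- function(family, n = 1000) {
  truth <- recovery_cases()[[family]]
  admin <- partsurv:::family_inv_survival(family, truth, 0.25)
  seed <- match(family, names(recovery_cases()))
  simulate_arm(true_arm_model(family, truth, "a"),
               censoring_spec(admin, 0), n, seed = seed)
}

# small survival dataset from explicit times/events
sdat <- function(time, event, ...) survival_dataset(time, event, ...)

# brute-force minimal-cost vial enumeration (independent oracle for the DP)
brute_force_vial_cost <- function(mg, vials) {
  counts <- lapply(seq_len(nrow(vials)), function(i)
    0:ceiling(mg / vials$size[i]))
  grid <- expand.grid(counts)
  covered <- as.matrix(grid) %*% vials$size >= mg - 1e-9
  costs <- as.matrix(grid) %*% vials$price
  min(costs[covered])
}

# a slimmed-down reference scenario for fast pipeline tests
small_reference <- function(seed = 3) {
  ref <- make_reference_scenario(seed = seed, n_per_arm = 150)
  cfg <- unclass(ref$config)
  cfg$engine$cycle_length <- 1 / 12
  cfg$engine$horizon <- 25
  cfg$psa$n_draws <- 25
  ref$config <- validate_config(cfg)
  ref
}
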