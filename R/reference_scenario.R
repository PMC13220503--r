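#' Synthetic life table
#'
#' A smooth Gompertz-style general-population life table (annual death
#' probabilities rising exponentially with age), adequate for exercising the
#' severity-modifier machinery; it is a synthetic stand-in, not a national
#' life table.
#'
#' @param max_age last tabulated age.
#' @param a,b,c parameters of `qx = min(0.7, a * exp(b * age) + c)`.
#' @return data frame with columns `age`, `qx`.
#' @export
make_synthetic_life_table <- function(max_age = 110, a = 8e-5, b = 0.088,
                                      c = 5e-4) {
  age <- 0:max_age
  data.frame(age = age, qx = pmin(0.7, a * exp(b * age) + c))
}

# synthetic two-arm data-generating truth: Weibull comparator OS/PFS with the
# intervention curves obtained by proportional hazards (HR < 1), so the
# Weibull family is closed under the transform: scale_int = scale * hr^(-1/shape)
.reference_truth <- function(hr_os = 0.75, hr_pfs = 0.61) {
  os_shape <- 1.2; os_scale <- 2.2
  pfs_shape <- 1.1; pfs_scale <- 0.85
  list(
    comparator = list(
      os = true_arm_model("weibull", c(shape = os_shape, scale = os_scale),
                          "comparator"),
      pfs = true_arm_model("weibull", c(shape = pfs_shape, scale = pfs_scale),
                           "comparator")),
    intervention = list(
      os = true_arm_model("weibull",
                          c(shape = os_shape,
                            scale = os_scale * hr_os^(-1 / os_shape)),
                          "intervention"),
      pfs = true_arm_model("weibull",
                           c(shape = pfs_shape,
                             scale = pfs_scale * hr_pfs^(-1 / pfs_shape)),
                           "intervention")),
    hr_os = hr_os, hr_pfs = hr_pfs
  )
}

#' Build the synthetic reference scenario
#'
#' A complete, runnable pipeline configuration plus simulated two-arm
#' OS/PFS datasets, mirroring a first-line appraisal: the intervention adds a
#' biologic to the comparator chemotherapy backbone, improving OS (HR 0.75)
#' and PFS (HR 0.61) at extra acquisition and administration cost. Utilities
#' (0.77 progression-free / 0.68 progressed), state costs (133 and 273 GBP
#' per month), the 6,265 GBP terminal-care cost, fixed mean treatment
#' durations (5 and 4 months) and administration/monitoring costs in the
#' 819-1,527 GBP per month range are the non-confidential published inputs;
#' tender prices and body-metric distributions are synthetic stand-ins.
#'
#' @param seed integer seed controlling the simulated trial.
#' @param n_per_arm subjects per arm (default 500).
#' @return list of class `reference_scenario` with `config` (see
#'   [validate_config()]) and `datasets` (`intervention`/`comparator`, each
#'   with `os` and `pfs` [survival_dataset()]s), plus the generating `truth`.
#' @export
make_reference_scenario <- function(seed = 1, n_per_arm = 500) {
  truth <- .reference_truth()
  cens <- censoring_spec(admin_time = 3, dropout_rate = 0.03)
  datasets <- list(
    intervention = simulate_linked_endpoints(
      truth$intervention$os, truth$intervention$pfs, cens, n_per_arm,
      seed = seed),
    comparator = simulate_linked_endpoints(
      truth$comparator$os, truth$comparator$pfs, cens, n_per_arm,
      seed = seed + 1000L)
  )

  backbone <- list(
    list(name = "oxaliplatin", dose_type = "per_bsa", dose = 85,
         interval_weeks = 2, rdi = 0.9,
         vials = list(list(size = 50, price = 18),
                      list(size = 100, price = 30))),
    list(name = "folinic_acid", dose_type = "flat", dose = 350,
         interval_weeks = 2, rdi = 1,
         vials = list(list(size = 350, price = 9)))
  )
  biologic <- list(name = "biologic", dose_type = "per_kg", dose = 5,
                   interval_weeks = 2, rdi = 0.9, tendered = TRUE,
                   vial_sizes = c(100, 400),
                   vial_price_factors = c(1, 3.8))

  config <- list(
    seed = seed,
    time_unit = "years",
    currency_year = "2023/24",
    cohort = list(start_age = 60, prop_female = 0.40),
    engine = list(cycle_length = 1 / 52, horizon = 40,
                  discount_qaly = 0.035, discount_cost = 0.035),
    fit = list(criterion = "aic", preferred_shape = "increasing"),
    utilities = list(pf = 0.77, pd = 0.68, age_decrement_per_year = 0.003,
                     ae_disutility = list(intervention = 0.015,
                                          comparator = 0.010)),
    costs = list(
      state_pf_monthly = 133, state_pd_monthly = 273, terminal = 6265,
      admin_monthly = list(intervention = 1527, comparator = 819),
      ae_cost = list(intervention = 450, comparator = 300),
      vial_sharing = FALSE,
      price_statistic = "mean",
      # synthetic tender prices (GBP per 100 mg vial-equivalent) and shares
      tender_prices = data.frame(
        price = c(210, 195, 240, 185, 225, 205, 250, 190),
        share = c(0.22, 0.18, 0.08, 0.15, 0.10, 0.12, 0.05, 0.10))
    ),
    regimens = list(intervention = c(backbone, list(biologic)),
                    comparator = backbone),
    ttd = list(intervention = 5 / 12, comparator = 4 / 12),
    ttd_unit = "years",
    bodies = list(
      weight = list(male = c(log(78), 0.18), female = c(log(66), 0.19)),
      bsa = list(male = c(log(1.95), 0.08), female = c(log(1.75), 0.08))),
    severity = list(prop_12 = 0.85, abs_12 = 12, prop_17 = 0.95, abs_17 = 18),
    genpop = list(life_table = make_synthetic_life_table(),
                  utility_norm_at_start = 0.80,
                  utility_norm_slope_per_year = 0.004),
    subsequent_qaly_addition = 0.8,
    thresholds = c(20000, 30000),
    scenarios = c("base", "alt_distribution", "hazard_ratio",
                  "median_price", "vial_sharing"),
    hr_scenario = list(os = 0.75, pfs = 0.61),
    psa = list(n_draws = 500, se_frac = 0.10, sample_survival = TRUE,
               sample_price = FALSE, vcov_scale = 1)
  )
  structure(list(config = validate_config(config), datasets = datasets,
                 truth = truth),
            class = "reference_scenario")
}
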