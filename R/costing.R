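#' Market-share-weighted tender price
#'
#' @param tender_prices data frame (or list coercible to one) with columns
#'   `price` (GBP) and `share` (market shares summing to 1).
#' @param statistic `"mean"` (share-weighted mean) or `"median"` (smallest
#'   price whose cumulative share reaches 0.5).
#' @return a single price in GBP.
#' @export
weighted_price <- function(tender_prices, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  tp <- as.data.frame(tender_prices)
  assert_that(nrow(tp) >= 1 && all(c("price", "share") %in% names(tp)),
              "tender_prices needs columns price and share",
              class = "partsurv_config_error")
  assert_that(all(tp$price >= 0) && all(tp$share >= 0),
              "tender_prices: prices and shares must be non-negative",
              class = "partsurv_config_error")
  assert_that(abs(sum(tp$share) - 1) <= 1e-9,
              "tender_prices: market shares must sum to 1",
              class = "partsurv_config_error")
  if (statistic == "mean") return(sum(tp$price * tp$share))
  tp <- tp[order(tp$price), ]
  tp$price[which(cumsum(tp$share) >= 0.5 - 1e-12)[1]]
}

#' Body-metric distribution for dose calculation
#'
#' Log-normal (or empirical) distributions of body weight (kg) and body
#' surface area (m^2) by sex, summarised on a deterministic quantile grid so
#' that expected vial counts are reproducible without Monte Carlo.
#'
#' @param weight,bsa per-metric specification: either
#'   `list(male = c(meanlog, sdlog), female = c(meanlog, sdlog))` or
#'   `list(male = <numeric samples>, female = <numeric samples>)`.
#' @param prop_female proportion of the cohort that is female.
#' @param n_quantiles grid size per sex (default 199).
#' @return object of class `body_metric_distribution` with `draw(metric)`
#'   returning a data frame `value`, `weight`.
#' @export
body_metric_distribution <- function(weight, bsa = NULL, prop_female = 0.4,
                                     n_quantiles = 199) {
  assert_that(is_number(prop_female) && prop_female >= 0 && prop_female <= 1,
              "prop_female must lie in [0, 1]",
              class = "partsurv_config_error")
  probs <- seq_len(n_quantiles) / (n_quantiles + 1)
  grid_for <- function(sexspec) {
    if (length(sexspec) == 2 && is.null(dim(sexspec)))
      stats::qlnorm(probs, sexspec[1], sexspec[2])
    else
      quantile(sexspec, probs, names = FALSE, type = 7)
  }
  build <- function(spec) {
    if (is.null(spec)) return(NULL)
    vm <- grid_for(spec$male)
    vf <- grid_for(spec$female)
    assert_that(all(c(vm, vf) > 0), "body metrics must be positive",
                class = "partsurv_config_error")
    data.frame(value = c(vm, vf),
               weight = c(rep((1 - prop_female) / n_quantiles, n_quantiles),
                          rep(prop_female / n_quantiles, n_quantiles)))
  }
  grids <- list(weight = build(weight), bsa = build(bsa))
  structure(list(draw = function(metric) {
    g <- grids[[metric]]
    assert_that(!is.null(g), "no ", metric, " distribution configured",
                class = "partsurv_config_error")
    g
  }, prop_female = prop_female), class = "body_metric_distribution")
}

# cheapest whole-vial combination covering each dose from 1 mg up to `mg_max`,
# by dynamic programming on 1 mg units (cost minimisation, not waste
# minimisation: the two differ when price per mg varies across vial sizes)
.combo_table <- function(mg_max, vial_options) {
  sizes <- as.integer(ceiling(vial_options$size))
  prices <- vial_options$price
  m <- max(1L, as.integer(ceiling(mg_max - 1e-9)))
  best <- rep(Inf, m)
  nv <- rep(0L, m)
  for (target in seq_len(m)) {
    for (i in seq_along(sizes)) {
      rest <- target - sizes[i]
      cand <- prices[i] + if (rest <= 0) 0 else best[rest]
      if (cand < best[target]) {
        best[target] <- cand
        nv[target] <- 1L + if (rest <= 0) 0L else nv[rest]
      }
    }
  }
  list(cost = best, n_vials = nv)
}

#' Cheapest whole-vial combination for a single dose
#'
#' @param mg required dose in mg.
#' @param vial_options data frame `size`, `price`.
#' @return list with `cost` (GBP) and `n_vials`.
#' @export
cheapest_vial_combo <- function(mg, vial_options) {
  dp <- .combo_table(mg, as.data.frame(vial_options))
  m <- max(1L, as.integer(ceiling(mg - 1e-9)))
  list(cost = dp$cost[m], n_vials = dp$n_vials[m])
}

#' Expected drug cost per administration from vial counting
#'
#' For each point of the body-metric quantile grid, the required dose in mg is
#' `dose x metric x RDI` (or `dose x RDI` for flat dosing). Without vial
#' sharing the cost is the cheapest whole-vial combination covering the
#' required dose; with sharing the cost is the required mg times the cheapest
#' price per mg on the menu. The result is the expectation over the grid.
#'
#' @param dose_rule list with `type` (`"per_kg"`, `"per_bsa"` or `"flat"`) and
#'   `dose` (mg/kg, mg/m^2 or mg).
#' @param bodies a [body_metric_distribution()] (unused for flat dosing).
#' @param rdi relative dose intensity in (0, 1].
#' @param vial_options data frame with columns `size` (mg) and `price` (GBP).
#' @param sharing logical: vial sharing assumed?
#' @return list: `expected_cost` (GBP per administration), `vial_counts`
#'   (distribution over number of vials; `NA` count under sharing).
#' @export
expected_vial_cost <- function(dose_rule, bodies = NULL, rdi = 1,
                               vial_options, sharing = FALSE) {
  assert_that(is_number(rdi) && rdi > 0 && rdi <= 1, "rdi must lie in (0, 1]",
              class = "partsurv_config_error")
  vial_options <- as.data.frame(vial_options)
  assert_that(nrow(vial_options) >= 1 &&
                all(c("size", "price") %in% names(vial_options)) &&
                all(vial_options$size > 0) && all(vial_options$price >= 0),
              "vial_options needs positive sizes and non-negative prices",
              class = "partsurv_config_error")
  if (dose_rule$type == "flat") {
    grid <- data.frame(value = 1, weight = 1)
  } else {
    metric <- switch(dose_rule$type, per_kg = "weight", per_bsa = "bsa",
                     stop_partsurv("unknown dose rule '", dose_rule$type, "'",
                                   class = "partsurv_config_error"))
    assert_that(inherits(bodies, "body_metric_distribution"),
                "bodies must be a body_metric_distribution",
                class = "partsurv_config_error")
    grid <- bodies$draw(metric)
  }
  mg <- dose_rule$dose * grid$value * rdi
  if (sharing) {
    per_mg <- min(vial_options$price / vial_options$size)
    return(list(expected_cost = sum(mg * per_mg * grid$weight),
                vial_counts = data.frame(n_vials = NA_integer_, prob = 1)))
  }
  dp <- .combo_table(max(mg), vial_options)
  idx <- pmax(1L, as.integer(ceiling(mg - 1e-9)))
  cost <- dp$cost[idx]
  nv <- dp$n_vials[idx]
  counts <- tapply(grid$weight, nv, sum)
  list(expected_cost = sum(cost * grid$weight),
       vial_counts = data.frame(n_vials = as.integer(names(counts)),
                                prob = as.numeric(counts)))
}

#' A treatment regimen component
#'
#' @param name component label.
#' @param dose_type `"per_kg"`, `"per_bsa"` or `"flat"`.
#' @param dose dose in mg/kg, mg/m^2 or mg.
#' @param interval_weeks weeks between administrations.
#' @param rdi relative dose intensity in (0, 1].
#' @param vial_options data frame `size`, `price`.
#' @return a `regimen_component`.
#' @export
regimen_component <- function(name, dose_type, dose, interval_weeks,
                              rdi = 1, vial_options) {
  assert_that(is_number(dose) && dose > 0 && is_number(interval_weeks) &&
                interval_weeks > 0,
              "dose and interval_weeks must be positive",
              class = "partsurv_config_error")
  structure(list(name = name, dose_rule = list(type = dose_type, dose = dose),
                 interval_weeks = interval_weeks, rdi = rdi,
                 vial_options = as.data.frame(vial_options)),
            class = "regimen_component")
}

#' Acquisition cost of a regimen per model cycle
#'
#' @param regimen list of [regimen_component()]s.
#' @param bodies a [body_metric_distribution()].
#' @param sharing vial-sharing flag.
#' @param cycle_length model cycle length in years (1 week = 1/52 year).
#' @param admin_monthly administration/monitoring cost in GBP per month
#'   (prorated per cycle in the returned total).
#' @return list: `per_component` (GBP per cycle while on treatment, named),
#'   `acquisition_per_cycle`, `admin_per_cycle`, `total_per_cycle`.
#' @export
regimen_cycle_cost <- function(regimen, bodies, sharing = FALSE,
                               cycle_length = 1 / 52, admin_monthly = 0) {
  weeks_per_cycle <- cycle_length * 52
  per_component <- vapply(regimen, function(comp) {
    evc <- expected_vial_cost(comp$dose_rule, bodies, comp$rdi,
                              comp$vial_options, sharing)
    evc$expected_cost * weeks_per_cycle / comp$interval_weeks
  }, numeric(1))
  names(per_component) <- vapply(regimen, `[[`, character(1), "name")
  acq <- sum(per_component)
  admin <- admin_monthly * 12 * cycle_length
  list(per_component = per_component, acquisition_per_cycle = acq,
       admin_per_cycle = admin, total_per_cycle = acq + admin)
}

#' Consolidated per-arm cost inputs for the engine
#'
#' @param acquisition_weekly drug acquisition cost in GBP per week on
#'   treatment (from [regimen_cycle_cost()] divided by the cycle's weeks, or
#'   supplied directly).
#' @param admin_monthly administration/monitoring GBP per month on treatment.
#' @param state_pf_monthly,state_pd_monthly health-state costs, GBP per month.
#' @param terminal one-off terminal-care cost at death, GBP.
#' @param ae_cost one-off expected adverse-event cost at entry, GBP.
#' @return an `arm_cost_spec`.
#' @export
arm_cost_spec <- function(acquisition_weekly = 0, admin_monthly = 0,
                          state_pf_monthly = 0, state_pd_monthly = 0,
                          terminal = 0, ae_cost = 0) {
  vals <- c(acquisition_weekly, admin_monthly, state_pf_monthly,
            state_pd_monthly, terminal, ae_cost)
  assert_that(all(is.finite(vals)) && all(vals >= 0),
              "all cost inputs must be non-negative",
              class = "partsurv_config_error")
  structure(list(acquisition_weekly = acquisition_weekly,
                 admin_monthly = admin_monthly,
                 state_pf_monthly = state_pf_monthly,
                 state_pd_monthly = state_pd_monthly,
                 terminal = terminal, ae_cost = ae_cost),
            class = "arm_cost_spec")
}
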