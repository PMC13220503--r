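#' Specification of a partitioned survival model arm
#'
#' Three health states (progression-free, progressed, dead). State occupancy
#' is read directly off the OS and PFS curves: at each cycle boundary,
#' `dead = 1 - S_OS(t)`, `PF = min(S_PFS(t), S_OS(t))` and the remainder is
#' progressed disease. PFS coordinates above OS (possible with digitised
#' curves) are clipped to OS and counted.
#'
#' @param os_model,pfs_model [surv_fn()] objects for OS and PFS.
#' @param ttd either a [surv_fn()] (time-to-treatment-discontinuation curve,
#'   capped at PF), a positive number (fixed mean treatment duration in years:
#'   on-treatment equals PF occupancy until that time, 0 after), or a named
#'   list of either, one per regimen component. `NULL` means treated while
#'   progression-free.
#' @param cycle_length cycle length in years (default 1/52, one week).
#' @param horizon time horizon in years (default 40).
#' @param discount_qaly,discount_cost annual discount rates (default 0.035).
#' @param start_age cohort age at entry (default 60).
#' @param prop_female proportion female (default 0.40).
#' @param mortality_floor optional life-table hazard floor applied to OS
#'   (data frame `age`, `qx`); default `NULL` (off).
#' @return an object of class `partsa_spec`.
#' @export
partsa_spec <- function(os_model, pfs_model, ttd = NULL,
                        cycle_length = 1 / 52, horizon = 40,
                        discount_qaly = 0.035, discount_cost = 0.035,
                        start_age = 60, prop_female = 0.40,
                        mortality_floor = NULL) {
  assert_that(inherits(os_model, "surv_fn") && inherits(pfs_model, "surv_fn"),
              "os_model and pfs_model must be surv_fn objects",
              class = "partsurv_parameter_error")
  assert_that(is_number(cycle_length) && cycle_length > 0 &&
                cycle_length <= horizon,
              "cycle_length must be positive and at most the horizon",
              class = "partsurv_parameter_error")
  for (r in c(discount_qaly, discount_cost))
    assert_that(is_number(r) && r >= 0 && r < 1,
                "discount rates must lie in [0, 1)",
                class = "partsurv_parameter_error")
  structure(list(os_model = os_model, pfs_model = pfs_model, ttd = ttd,
                 cycle_length = cycle_length, horizon = horizon,
                 discount_qaly = discount_qaly, discount_cost = discount_cost,
                 start_age = start_age, prop_female = prop_female,
                 mortality_floor = mortality_floor),
            class = "partsa_spec")
}

.ttd_on_treatment <- function(ttd, t, pf) {
  if (is.null(ttd)) return(pf)
  if (inherits(ttd, "surv_fn")) return(pmin(eval_surv(ttd, t), pf))
  if (is_number(ttd)) return(ifelse(t < ttd, pf, 0))
  stop_partsurv("ttd must be a surv_fn, a positive number, or NULL",
                class = "partsurv_parameter_error")
}

#' State occupancy traces for one arm
#'
#' Evaluates occupancy at every cycle boundary from 0 to the horizon. The
#' three occupancies sum to one by construction; the number of cycle
#' boundaries at which the PFS curve had to be clipped to OS is recorded in
#' attribute `n_clipped`.
#'
#' @param spec a [partsa_spec()].
#' @return a data frame of class `state_trace`: `time`, `age`, `pf`, `pd`,
#'   `dead`, and one `on_trt*` column per treatment component.
#' @export
build_traces <- function(spec) {
  assert_that(inherits(spec, "partsa_spec"), "spec must be a partsa_spec",
              class = "partsurv_parameter_error")
  t <- seq(0, spec$horizon, by = spec$cycle_length)
  if (t[length(t)] < spec$horizon) t <- c(t, spec$horizon)
  s_os <- eval_surv(spec$os_model, t)
  if (!is.null(spec$mortality_floor))
    s_os <- .apply_mortality_floor(s_os, t, spec$start_age,
                                   spec$mortality_floor)
  s_pfs <- eval_surv(spec$pfs_model, t)
  n_clipped <- sum(s_pfs > s_os + 1e-12)
  pf <- pmin(s_pfs, s_os)
  dead <- 1 - s_os
  pd <- pmax(s_os - pf, 0)
  out <- data.frame(time = t, age = spec$start_age + t,
                    pf = pf, pd = pd, dead = dead)
  ttd <- spec$ttd
  if (is.null(ttd) || inherits(ttd, "surv_fn") || is_number(ttd)) {
    out$on_trt <- .ttd_on_treatment(ttd, t, pf)
  } else {
    for (nm in names(ttd))
      out[[paste0("on_trt_", nm)]] <- .ttd_on_treatment(ttd[[nm]], t, pf)
    out$on_trt <- do.call(pmax, out[paste0("on_trt_", names(ttd))])
  }
  structure(out, n_clipped = n_clipped, cycle_length = spec$cycle_length,
            class = c("state_trace", "data.frame"))
}

# life-table hazard floor: S_OS may not decline slower than general-population
# survival from the cohort's age
.apply_mortality_floor <- function(s_os, t, start_age, life_table) {
  qx <- life_table$qx[match(pmin(floor(start_age + t), max(life_table$age)),
                            life_table$age)]
  h_gen <- -log(pmax(1 - qx, 1e-12))
  dt <- diff(t)
  h_model <- -diff(log(pmax(s_os, 1e-300))) / dt
  h_mid <- pmax(h_model, h_gen[-length(h_gen)])
  c(1, exp(-cumsum(h_mid * dt))) * s_os[1]
}

#' Utility inputs for QALY accumulation
#'
#' @param u_pf,u_pd utilities for the progression-free and progressed states
#'   (in `[0, 1]`; `u_pf >= u_pd` enforced unless `allow_inversion`).
#' @param age_decrement_per_year multiplicative utility decrement per year of
#'   age beyond the cohort's start age (e.g. 0.003 means a 70-year-old's
#'   utilities are scaled by 0.97 relative to a 60-year-old baseline). The
#'   underlying published regression coefficients are an input, not hard-coded.
#' @param ae_disutility one-off expected QALY loss from treatment-related
#'   adverse events, applied at model entry (already weighted by per-arm event
#'   probabilities).
#' @param allow_inversion permit `u_pd > u_pf`.
#' @return an object of class `utility_spec`.
#' @export
utility_spec <- function(u_pf, u_pd, age_decrement_per_year = 0,
                         ae_disutility = 0, allow_inversion = FALSE) {
  assert_that(is_number(u_pf) && u_pf >= 0 && u_pf <= 1 &&
                is_number(u_pd) && u_pd >= 0 && u_pd <= 1,
              "utilities must lie in [0, 1]", class = "partsurv_parameter_error")
  if (!allow_inversion)
    assert_that(u_pf >= u_pd, "u_pf must be >= u_pd",
                class = "partsurv_parameter_error")
  assert_that(is_number(age_decrement_per_year) && age_decrement_per_year >= 0 &&
                age_decrement_per_year < 1,
              "age_decrement_per_year must lie in [0, 1)",
              class = "partsurv_parameter_error")
  structure(list(u_pf = u_pf, u_pd = u_pd,
                 age_decrement_per_year = age_decrement_per_year,
                 ae_disutility = ae_disutility),
            class = "utility_spec")
}

# discounted trapezoidal accumulation over the trace: per cycle, the mean of
# the boundary values of `values`, times cycle length, discounted at the
# cycle midpoint
.accumulate <- function(t, values, rate) {
  dt <- diff(t)
  mid <- (t[-length(t)] + t[-1]) / 2
  disc <- (1 + rate)^(-mid)
  sum(dt * (values[-length(values)] + values[-1]) / 2 * disc)
}

#' Discounted QALYs and life-years from a trace
#'
#' QALY increments per cycle are `cycle_length * [PF * u_pf(age) +
#' PD * u_pd(age)]`, half-cycle corrected by the trapezoid rule and discounted
#' at cycle midpoints; the adverse-event disutility is charged once at entry.
#' Life-years use utility 1 in both alive states.
#'
#' @param trace a `state_trace` from [build_traces()].
#' @param utilities a [utility_spec()].
#' @param discount_rate annual discount rate for QALYs.
#' @return list: `qalys` (discounted), `ly` (discounted), `ly_undiscounted`.
#' @export
accumulate_qalys <- function(trace, utilities, discount_rate = 0.035) {
  assert_that(inherits(trace, "state_trace"), "trace must be a state_trace",
              class = "partsurv_parameter_error")
  assert_that(inherits(utilities, "utility_spec"),
              "utilities must be a utility_spec",
              class = "partsurv_parameter_error")
  t <- trace$time
  agefac <- pmax(1 - utilities$age_decrement_per_year * (trace$age - trace$age[1]),
                 0)
  qw <- trace$pf * utilities$u_pf * agefac + trace$pd * utilities$u_pd * agefac
  alive <- trace$pf + trace$pd
  list(
    qalys = .accumulate(t, qw, discount_rate) - utilities$ae_disutility,
    ly = .accumulate(t, alive, discount_rate),
    ly_undiscounted = .accumulate(t, alive, 0)
  )
}

#' Discounted, itemised costs from a trace
#'
#' State costs accrue per month of occupancy; acquisition and
#' administration/monitoring costs accrue on the on-treatment proportion;
#' the terminal cost is charged on each cycle's new deaths, discounted at the
#' cycle of death; adverse-event costs are charged once at entry.
#'
#' @param trace a `state_trace`.
#' @param costs an `arm_cost_spec` from [arm_cost_spec()].
#' @param discount_rate annual discount rate for costs.
#' @return named list: `acquisition`, `admin`, `state`, `terminal`, `ae`,
#'   `total` (all discounted GBP).
#' @export
accumulate_costs <- function(trace, costs, discount_rate = 0.035) {
  assert_that(inherits(trace, "state_trace"), "trace must be a state_trace",
              class = "partsurv_parameter_error")
  assert_that(inherits(costs, "arm_cost_spec"),
              "costs must be an arm_cost_spec",
              class = "partsurv_parameter_error")
  t <- trace$time
  months_per_year <- 12
  state_monthly <- trace$pf * costs$state_pf_monthly +
    trace$pd * costs$state_pd_monthly
  state <- .accumulate(t, state_monthly * months_per_year, discount_rate)
  on_cost_yearly <- trace$on_trt * (costs$acquisition_weekly * 52 +
                                      costs$admin_monthly * months_per_year)
  acq <- .accumulate(t, trace$on_trt * costs$acquisition_weekly * 52,
                     discount_rate)
  admin <- .accumulate(t, trace$on_trt * costs$admin_monthly * months_per_year,
                       discount_rate)
  new_deaths <- diff(trace$dead)
  mid <- (t[-length(t)] + t[-1]) / 2
  terminal <- costs$terminal * sum(new_deaths * (1 + discount_rate)^(-mid))
  ae <- costs$ae_cost
  list(acquisition = acq, admin = admin, state = state, terminal = terminal,
       ae = ae, total = acq + admin + state + terminal + ae)
}

#' Run the model for two arms and form increments
#'
#' Both arms must share cycle structure, horizon and discounting. Costs and
#' QALYs attributable to subsequent treatment lines are excluded by
#' construction (they enter only the severity-modifier shortfall
#' computation, never these increments).
#'
#' @param spec_intervention,spec_comparator [partsa_spec()] objects.
#' @param utilities a [utility_spec()] or list with per-arm entries
#'   `intervention`, `comparator`.
#' @param costs_intervention,costs_comparator [arm_cost_spec()] objects.
#' @return object of class `comparison_result`: per-arm `ly`, `qalys`, `cost`
#'   (with items), and increments `d_ly`, `d_qalys`, `d_cost`.
#' @export
run_comparison <- function(spec_intervention, spec_comparator, utilities,
                           costs_intervention, costs_comparator) {
  for (fld in c("cycle_length", "horizon", "discount_qaly", "discount_cost"))
    assert_that(identical(spec_intervention[[fld]], spec_comparator[[fld]]),
                "arms differ in ", fld, class = "partsurv_config_error")
  u_int <- if (inherits(utilities, "utility_spec")) utilities
           else utilities$intervention
  u_com <- if (inherits(utilities, "utility_spec")) utilities
           else utilities$comparator
  arm <- function(spec, u, costs) {
    trace <- build_traces(spec)
    q <- accumulate_qalys(trace, u, spec$discount_qaly)
    cost <- accumulate_costs(trace, costs, spec$discount_cost)
    list(trace = trace, qalys = q$qalys, ly = q$ly,
         ly_undiscounted = q$ly_undiscounted, cost = cost)
  }
  int <- arm(spec_intervention, u_int, costs_intervention)
  com <- arm(spec_comparator, u_com, costs_comparator)
  structure(list(
    intervention = int, comparator = com,
    d_ly = int$ly_undiscounted - com$ly_undiscounted,
    d_ly_discounted = int$ly - com$ly,
    d_qalys = int$qalys - com$qalys,
    d_cost = int$cost$total - com$cost$total
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>\n",
      sprintf("  LYG (undiscounted): %.4f\n", x$d_ly),
      sprintf("  incremental QALYs (discounted): %.4f\n", x$d_qalys),
      sprintf("  incremental cost (discounted): %.2f\n", x$d_cost), sep = "")
  invisible(x)
}
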