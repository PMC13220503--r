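#' Fit all families to every arm and endpoint, with joint selection
#'
#' Fits the seven-family menu to OS and PFS in both arms and applies the joint
#' selection policy per endpoint (same family across arms).
#'
#' @param datasets list with `intervention` and `comparator`, each containing
#'   [survival_dataset()]s `os` and `pfs`.
#' @param config a `pipeline_config`.
#' @return list of class `evidence_fits`: per endpoint, `fits` (by arm) and
#'   `selection` (`base`, `sensitivity`).
#' @export
fit_evidence <- function(datasets, config) {
  horizon <- config$engine$horizon
  out <- lapply(setNames(nm = c("os", "pfs")), function(ep) {
    fits_by_arm <- lapply(datasets, function(arm_data)
      lapply(setNames(nm = surv_families()),
             function(f) fit_parametric(arm_data[[ep]], f)))
    sel <- select_families(fits_by_arm, horizon = horizon,
                           preferred_shape = config$fit$preferred_shape,
                           criterion = config$fit$criterion)
    list(fits = fits_by_arm, selection = sel)
  })
  structure(out, class = "evidence_fits")
}

# resolve regimen config entries into regimen_component objects; tendered
# components get vial prices of `unit_price * factor`
.resolve_regimen <- function(components, unit_price) {
  lapply(components, function(cmp) {
    vials <- if (isTRUE(cmp$tendered)) {
      data.frame(size = cmp$vial_sizes,
                 price = unit_price * cmp$vial_price_factors)
    } else {
      do.call(rbind, lapply(cmp$vials, function(v)
        data.frame(size = v$size, price = v$price)))
    }
    regimen_component(cmp$name, cmp$dose_type, cmp$dose, cmp$interval_weeks,
                      rdi = cmp$rdi %||% 1, vial_options = vials)
  })
}

.bodies_from_config <- function(config) {
  body_metric_distribution(weight = config$bodies$weight,
                           bsa = config$bodies$bsa,
                           prop_female = config$cohort$prop_female)
}

# per-arm engine cost spec under given price statistic / sharing flag
.arm_costs <- function(config, arm, price_statistic = NULL, sharing = NULL,
                       overrides = list()) {
  costs <- config$costs
  stat <- price_statistic %||% costs$price_statistic
  share_vials <- sharing %||% costs$vial_sharing
  unit_price <- overrides$unit_price %||%
    (if (!is.null(costs$tender_prices))
      weighted_price(costs$tender_prices, stat) else 0)
  regimen <- .resolve_regimen(config$regimens[[arm]], unit_price)
  bodies <- .bodies_from_config(config)
  acquisition_weekly <- sum(vapply(regimen, function(comp) {
    evc <- expected_vial_cost(comp$dose_rule, bodies, comp$rdi,
                              comp$vial_options, share_vials)
    evc$expected_cost / comp$interval_weeks
  }, numeric(1)))
  arm_cost_spec(
    acquisition_weekly = acquisition_weekly,
    admin_monthly = overrides$admin_monthly %||% costs$admin_monthly[[arm]],
    state_pf_monthly = overrides$state_pf_monthly %||% costs$state_pf_monthly,
    state_pd_monthly = overrides$state_pd_monthly %||% costs$state_pd_monthly,
    terminal = overrides$terminal %||% costs$terminal,
    ae_cost = overrides$ae_cost %||% (costs$ae_cost[[arm]] %||% 0)
  )
}

.arm_utilities <- function(config, arm, overrides = list()) {
  u <- config$utilities
  utility_spec(
    u_pf = overrides$u_pf %||% u$pf,
    u_pd = overrides$u_pd %||% u$pd,
    age_decrement_per_year = u$age_decrement_per_year,
    ae_disutility = u$ae_disutility[[arm]] %||% 0,
    allow_inversion = TRUE
  )
}

.arm_spec <- function(config, os_fn, pfs_fn, ttd) {
  partsa_spec(os_fn, pfs_fn, ttd = ttd,
              cycle_length = config$engine$cycle_length,
              horizon = config$engine$horizon,
              discount_qaly = config$engine$discount_qaly,
              discount_cost = config$engine$discount_cost,
              start_age = config$cohort$start_age,
              prop_female = config$cohort$prop_female)
}

# one full deterministic model evaluation; `curves` optionally overrides the
# per-arm survival functions, `families` the per-endpoint family choice
.evaluate_comparison <- function(config, fits, families = NULL, curves = NULL,
                                 price_statistic = NULL, sharing = NULL,
                                 util_overrides = list(),
                                 cost_overrides = list()) {
  if (is.null(curves)) {
    families <- families %||% list(os = fits$os$selection$base,
                                   pfs = fits$pfs$selection$base)
    curves <- lapply(setNames(nm = c("intervention", "comparator")),
                     function(arm) list(
                       os = surv_fn_model(fits$os$fits[[arm]][[families$os]]),
                       pfs = surv_fn_model(fits$pfs$fits[[arm]][[families$pfs]])))
  }
  specs <- lapply(setNames(nm = c("intervention", "comparator")),
                  function(arm) .arm_spec(config, curves[[arm]]$os,
                                          curves[[arm]]$pfs,
                                          config$ttd[[arm]]))
  utilities <- list(
    intervention = .arm_utilities(config, "intervention", util_overrides),
    comparator = .arm_utilities(config, "comparator", util_overrides))
  run_comparison(specs$intervention, specs$comparator, utilities,
                 .arm_costs(config, "intervention", price_statistic, sharing,
                            cost_overrides),
                 .arm_costs(config, "comparator", price_statistic, sharing,
                            cost_overrides))
}

#' Run the deterministic scenario battery
#'
#' Runs the base case plus the configured scenarios: `alt_distribution`
#' (the designated sensitivity families), `hazard_ratio` (intervention curves
#' constructed from the comparator fits via the configured meta-analytic
#' hazard ratios), `median_price` (weighted median tender price) and
#' `vial_sharing`. Scenarios whose required fit did not converge are skipped
#' with a log entry.
#'
#' @param config a `pipeline_config`.
#' @param fits an `evidence_fits` object.
#' @return data frame of class `scenario_table`: one row per scenario (base
#'   case first) with `d_ly`, `d_qalys`, `d_cost`, `icer`; skipped scenarios
#'   are recorded in attribute `log`.
#' @export
run_scenarios <- function(config, fits) {
  log <- character(0)
  rows <- list()
  add_row <- function(name, cmp) {
    res <- icer(cmp, thresholds = config$thresholds)
    rows[[name]] <<- data.frame(
      scenario = name, d_ly = cmp$d_ly, d_qalys = cmp$d_qalys,
      d_cost = cmp$d_cost,
      icer = if (is.character(res$icer)) NA_real_ else res$icer,
      icer_tag = if (is.character(res$icer)) res$icer else "",
      stringsAsFactors = FALSE)
  }
  add_row("base", .evaluate_comparison(config, fits))
  for (sc in setdiff(config$scenarios, "base")) {
    if (sc == "alt_distribution") {
      fam <- list(os = fits$os$selection$sensitivity,
                  pfs = fits$pfs$selection$sensitivity)
      if (anyNA(unlist(fam))) {
        log <- c(log, "alt_distribution skipped: no converged sensitivity family")
        next
      }
      add_row(sc, .evaluate_comparison(config, fits, families = fam))
    } else if (sc == "hazard_ratio") {
      base_fam <- list(os = fits$os$selection$base, pfs = fits$pfs$selection$base)
      comp <- list(
        os = surv_fn_model(fits$os$fits$comparator[[base_fam$os]]),
        pfs = surv_fn_model(fits$pfs$fits$comparator[[base_fam$pfs]]))
      curves <- list(
        intervention = list(
          os = apply_hazard_ratio(comp$os, config$hr_scenario$os),
          pfs = apply_hazard_ratio(comp$pfs, config$hr_scenario$pfs)),
        comparator = comp)
      add_row(sc, .evaluate_comparison(config, fits, curves = curves))
    } else if (sc == "median_price") {
      add_row(sc, .evaluate_comparison(config, fits,
                                       price_statistic = "median"))
    } else if (sc == "vial_sharing") {
      add_row(sc, .evaluate_comparison(config, fits, sharing = TRUE))
    } else {
      log <- c(log, paste0("unknown scenario '", sc, "' skipped"))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, log = log, class = c("scenario_table", "data.frame"))
}

# --- probabilistic sensitivity analysis ------------------------------------

.beta_mom_draw <- function(n, mean, se) {
  if (se <= 0 || mean <= 0 || mean >= 1) return(rep(mean, n))
  se <- min(se, 0.5 * sqrt(mean * (1 - mean)))
  v <- se^2
  a <- mean * (mean * (1 - mean) / v - 1)
  b <- (1 - mean) * (mean * (1 - mean) / v - 1)
  stats::rbeta(n, a, b)
}

.gamma_mom_draw <- function(n, mean, se) {
  if (se <= 0 || mean <= 0) return(rep(mean, n))
  stats::rgamma(n, shape = (mean / se)^2, rate = mean / se^2)
}

# multivariate-normal parameter draws on the estimation scale, mapped back to
# the natural scale (exp for positive-constrained parameters)
.draw_model_params <- function(model, n, vcov_scale = 1) {
  info <- family_info(model$family)
  if (vcov_scale <= 0)
    return(matrix(rep(model$params, each = n), nrow = n,
                  dimnames = list(NULL, names(model$params))))
  V <- model$vcov * vcov_scale
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev))) {
    warning("non-positive-definite covariance repaired (nearest PSD)")
    V <- as.matrix(Matrix::nearPD(V)$mat)
  }
  draws <- MASS::mvrnorm(n, mu = model$params_t, Sigma = V)
  if (n == 1) draws <- matrix(draws, nrow = 1)
  colnames(draws) <- names(model$params)
  for (p in info$positive) draws[, p] <- exp(draws[, p])
  draws
}

#' Probabilistic sensitivity analysis
#'
#' Survival parameters are drawn multivariate-normal on the estimation scale
#' from each fit's covariance; utilities are drawn beta and costs gamma, both
#' by method of moments around the deterministic means with standard errors of
#' `se_frac` times the mean (the dispersion inputs are configuration, not
#' published values). Each draw reruns the full two-arm model. Setting
#' `psa$vcov_scale = 0` and `psa$se_frac = 0` makes every draw reproduce the
#' deterministic result exactly.
#'
#' @param config a `pipeline_config`.
#' @param fits an `evidence_fits` object.
#' @param n_draws number of PSA draws (default from config).
#' @param seed RNG seed (default from config).
#' @return list of class `psa_result`: `draws` (data frame `d_ly`, `d_qalys`,
#'   `d_cost`), `mean` increments, `ceac` (threshold, probability
#'   cost-effective), `seed`, `n_draws`.
#' @export
run_psa <- function(config, fits, n_draws = NULL, seed = NULL) {
  n_draws <- n_draws %||% config$psa$n_draws
  seed <- seed %||% config$seed
  assert_that(is_number(n_draws) && n_draws >= 1, "n_draws must be >= 1",
              class = "partsurv_parameter_error")
  se_frac <- config$psa$se_frac
  vcov_scale <- if (isTRUE(config$psa$sample_survival))
    config$psa$vcov_scale else 0
  base_fam <- list(os = fits$os$selection$base, pfs = fits$pfs$selection$base)
  u <- config$utilities
  costs <- config$costs

  with_seed(seed, {
    par_draws <- lapply(setNames(nm = c("intervention", "comparator")),
                        function(arm) lapply(
                          setNames(nm = c("os", "pfs")), function(ep)
                            .draw_model_params(
                              fits[[ep]]$fits[[arm]][[base_fam[[ep]]]],
                              n_draws, vcov_scale)))
    u_pf <- .beta_mom_draw(n_draws, u$pf, se_frac * u$pf)
    u_pd <- .beta_mom_draw(n_draws, u$pd, se_frac * u$pd)
    state_pf <- .gamma_mom_draw(n_draws, costs$state_pf_monthly,
                                se_frac * costs$state_pf_monthly)
    state_pd <- .gamma_mom_draw(n_draws, costs$state_pd_monthly,
                                se_frac * costs$state_pd_monthly)
    terminal <- .gamma_mom_draw(n_draws, costs$terminal,
                                se_frac * costs$terminal)
    admin <- lapply(setNames(nm = c("intervention", "comparator")),
                    function(arm) .gamma_mom_draw(
                      n_draws, costs$admin_monthly[[arm]],
                      se_frac * costs$admin_monthly[[arm]]))
    base_price <- if (!is.null(costs$tender_prices))
      weighted_price(costs$tender_prices, costs$price_statistic) else 0
    price <- if (isTRUE(config$psa$sample_price))
      .gamma_mom_draw(n_draws, base_price, se_frac * base_price)
    else rep(base_price, n_draws)

    draws <- vector("list", n_draws)
    for (i in seq_len(n_draws)) {
      curves <- lapply(par_draws, function(arm) list(
        os = surv_fn_family(base_fam$os, arm$os[i, ]),
        pfs = surv_fn_family(base_fam$pfs, arm$pfs[i, ])))
      cmp <- .evaluate_comparison(
        config, fits, curves = curves,
        util_overrides = list(u_pf = u_pf[i], u_pd = u_pd[i]),
        cost_overrides = list(state_pf_monthly = state_pf[i],
                              state_pd_monthly = state_pd[i],
                              terminal = terminal[i],
                              unit_price = price[i]))
      # per-arm admin costs need separate overrides; recompute cheaply
      cmp$d_cost <- cmp$d_cost +
        .admin_adjust(cmp, admin$intervention[i], admin$comparator[i],
                      costs$admin_monthly, config)
      draws[[i]] <- c(d_ly = cmp$d_ly, d_qalys = cmp$d_qalys,
                      d_cost = cmp$d_cost)
    }
    draws <- as.data.frame(do.call(rbind, draws))
    grid <- seq(0, 50000, by = 1000)
    ceac <- data.frame(
      threshold = grid,
      prob_ce = vapply(grid, function(l)
        mean(l * draws$d_qalys - draws$d_cost > 0), numeric(1)))
    structure(list(draws = draws,
                   mean = c(d_ly = mean(draws$d_ly),
                            d_qalys = mean(draws$d_qalys),
                            d_cost = mean(draws$d_cost)),
                   ceac = ceac, seed = seed, n_draws = n_draws),
              class = "psa_result")
  })
}

# replace the deterministic admin cost difference with the drawn one, using
# the discounted on-treatment exposure already embedded in the run
.admin_adjust <- function(cmp, admin_int, admin_com, admin_base, config) {
  exp_int <- cmp$intervention$cost$admin / (admin_base$intervention * 12)
  exp_com <- cmp$comparator$cost$admin / (admin_base$comparator * 12)
  (admin_int - admin_base$intervention) * 12 * exp_int -
    (admin_com - admin_base$comparator) * 12 * exp_com
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result>", x$n_draws, "draws (seed", x$seed, ")\n")
  cat(sprintf("  mean dQALY %.4f, mean dCost %.2f\n",
              x$mean["d_qalys"], x$mean["d_cost"]))
  invisible(x)
}

# --- orchestration ----------------------------------------------------------

#' Run the full pipeline
#'
#' Executes the appraisal sequence end-to-end: ingest evidence (reconstructing
#' pseudo-IPD from any digitised curves), fit and select survival models,
#' run the partitioned survival model with costing, compute the economics
#' (ICER, iNMB, severity modifier), the scenario battery and the PSA, writing
#' every artifact to `run_dir` stamped with the seed and a config hash.
#'
#' @param config a `pipeline_config` (see [validate_config()]).
#' @param datasets evidence as in [fit_evidence()]; entries may be
#'   [digitized_curve()]s, which are reconstructed first, or
#'   [survival_dataset()]s, which are used as-is.
#' @param run_dir output directory (created if needed); `NULL` to skip writing.
#' @return list of class `pipeline_run`: `fits`, `base` (`comparison_result`),
#'   `econ` (`econ_result`), `shortfall`, `scenarios`, `psa`, `summary`.
#' @export
run_pipeline <- function(config, datasets, run_dir = NULL) {
  config <- validate_config(unclass(config))
  stamp <- list(seed = config$seed, config_hash = config_hash(config))

  datasets <- lapply(datasets, function(arm) lapply(arm, function(x) {
    if (inherits(x, "digitized_curve")) reconstruct_ipd(x) else x
  }))
  fits <- fit_evidence(datasets, config)
  scen <- run_scenarios(config, fits)
  base_cmp <- .evaluate_comparison(config, fits)

  gp <- config$genpop
  shortfall <- NULL
  weight <- 1.0
  if (!is.null(gp$life_table)) {
    ufun <- function(age) pmax(gp$utility_norm_at_start -
                                 gp$utility_norm_slope_per_year *
                                 (age - config$cohort$start_age), 0)
    gq <- general_population_qalys(config$cohort$start_age, gp$life_table,
                                   ufun, config$engine$discount_qaly)
    shortfall <- qaly_shortfall(base_cmp$comparator$qalys,
                                config$subsequent_qaly_addition, gq,
                                config$severity)
    weight <- shortfall$weight
  }
  econ <- icer(base_cmp, thresholds = config$thresholds,
               severity_weight = weight)
  psa <- run_psa(config, fits)

  summary <- list(
    seed = stamp$seed, config_hash = stamp$config_hash,
    base = list(d_ly = base_cmp$d_ly, d_qalys = base_cmp$d_qalys,
                d_cost = base_cmp$d_cost,
                icer = if (is.character(econ$icer)) NA else econ$icer,
                icer_tag = if (is.character(econ$icer)) econ$icer else "",
                inmb = as.list(econ$inmb),
                severity_weight = weight),
    shortfall = if (!is.null(shortfall)) unclass(shortfall),
    per_arm = list(
      intervention = list(ly = base_cmp$intervention$ly_undiscounted,
                          qalys = base_cmp$intervention$qalys,
                          cost = base_cmp$intervention$cost$total),
      comparator = list(ly = base_cmp$comparator$ly_undiscounted,
                        qalys = base_cmp$comparator$qalys,
                        cost = base_cmp$comparator$cost$total)),
    scenarios = as.data.frame(scen),
    psa = list(n_draws = psa$n_draws, mean = as.list(psa$mean),
               prob_ce_20k = psa$ceac$prob_ce[psa$ceac$threshold == 20000]),
    warnings = list(
      pfs_clipped_cycles =
        attr(base_cmp$intervention$trace, "n_clipped") +
        attr(base_cmp$comparator$trace, "n_clipped"),
      scenario_log = attr(scen, "log"))
  )

  if (!is.null(run_dir)) {
    dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, name) utils::write.table(
      cbind(df, config_hash = stamp$config_hash, seed = stamp$seed),
      file.path(run_dir, name), sep = "\t", row.names = FALSE, quote = FALSE)
    fit_tab <- do.call(rbind, lapply(c("os", "pfs"), function(ep)
      do.call(rbind, lapply(names(fits[[ep]]$fits), function(arm) {
        tab <- do.call(rbind, lapply(fits[[ep]]$fits[[arm]], function(f)
          data.frame(converged = isTRUE(f$converged),
                     loglik = f$loglik %||% NA_real_,
                     aic = f$aic %||% NA_real_, bic = f$bic %||% NA_real_,
                     hazard_shape = if (isTRUE(f$converged))
                       classify_hazard_shape(f, config$engine$horizon)
                     else NA_character_,
                     params = if (isTRUE(f$converged))
                       paste(names(f$params), signif(f$params, 6),
                             sep = "=", collapse = ";") else "")))
        cbind(endpoint = ep, arm = arm, family = rownames(tab), tab)
      }))))
    wt(fit_tab, "fits.tsv")
    wt(as.data.frame(base_cmp$intervention$trace), "trace_intervention.tsv")
    wt(as.data.frame(base_cmp$comparator$trace), "trace_comparator.tsv")
    wt(as.data.frame(scen), "scenario_table.tsv")
    wt(psa$ceac, "ceac.tsv")
    jsonlite::write_json(summary, file.path(run_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }

  structure(list(fits = fits, base = base_cmp, econ = econ,
                 shortfall = shortfall, scenarios = scen, psa = psa,
                 summary = summary),
            class = "pipeline_run")
}

#' Summarise a completed run
#'
#' Tabulates per-arm life-years, QALYs and costs, increments, the ICER and
#' iNMB. In redacted mode all monetary figures are suppressed, mirroring the
#' confidentiality handling under which only incremental QALYs and life-years
#' can be made public.
#'
#' @param run a `pipeline_run`, or a run directory containing
#'   `run_summary.json`.
#' @param redacted suppress prices, costs, ICERs and iNMB.
#' @return the rendered lines, invisibly; also printed.
#' @export
report_run <- function(run, redacted = FALSE) {
  s <- if (inherits(run, "pipeline_run")) run$summary
  else {
    f <- file.path(run, "run_summary.json")
    assert_that(file.exists(f), "incomplete run: missing ", f,
                class = "partsurv_config_error")
    jsonlite::read_json(f, simplifyVector = TRUE)
  }
  fmt <- function(x, d = 3) formatC(as.numeric(x), format = "f", digits = d)
  lines <- c(
    paste0("Run ", s$config_hash, " (seed ", s$seed, ")"),
    "",
    paste0("  Incremental LYG (undiscounted): ", fmt(s$base$d_ly)),
    paste0("  Incremental QALYs (discounted): ", fmt(s$base$d_qalys)),
    paste0("  Severity-modifier weight:       x", fmt(s$base$severity_weight, 1))
  )
  if (!redacted) {
    inmb <- unlist(s$base$inmb)
    # re-verify the iNMB identity at render time
    for (i in seq_along(inmb)) {
      lam <- as.numeric(sub("at_", "", names(inmb)[i]))
      stopifnot(abs(inmb[i] - (lam * s$base$severity_weight * s$base$d_qalys -
                                 s$base$d_cost)) < 1e-6)
    }
    lines <- c(lines,
      paste0("  Incremental cost (GBP):         ", fmt(s$base$d_cost, 2)),
      paste0("  ICER (GBP/QALY):                ",
             if (is.null(s$base$icer) || is.na(s$base$icer)) s$base$icer_tag
             else fmt(s$base$icer, 0)),
      vapply(seq_along(inmb), function(i)
        paste0("  iNMB ", names(inmb)[i], ": ", fmt(inmb[i], 2)),
        character(1)))
  }
  lines <- c(lines, "", paste0("  Scenarios: ",
                               nrow(as.data.frame(s$scenarios)), " run"))
  cat(lines, sep = "\n")
  invisible(lines)
}
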