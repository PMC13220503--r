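.config_keys <- c(
  "seed", "time_unit", "currency_year", "cohort", "engine", "fit",
  "utilities", "costs", "regimens", "ttd", "ttd_unit", "bodies", "severity",
  "genpop", "subsequent_qaly_addition", "thresholds", "scenarios",
  "hr_scenario", "psa", "evidence"
)

#' Validate and normalise a pipeline configuration
#'
#' Checks the configuration schema (unknown top-level keys are rejected,
#' required blocks present, market shares summing to one, discount rates and
#' utilities in range), fills defaults, and normalises units: internal time is
#' always years, so `ttd_unit: months` entries are divided by 12 (the
#' conversion factor is recorded in attribute `unit_conversions`).
#'
#' @param config a nested list, e.g. from [load_config()] or
#'   [make_reference_scenario()].
#' @return the validated, normalised config (class `pipeline_config`).
#' @export
validate_config <- function(config) {
  assert_that(is.list(config), "config must be a list",
              class = "partsurv_config_error")
  unknown <- setdiff(names(config), .config_keys)
  assert_that(length(unknown) == 0,
              "unknown config key(s): ", paste(unknown, collapse = ", "),
              class = "partsurv_config_error")
  assert_that(identical(config$time_unit %||% "years", "years"),
              "time_unit: only 'years' is supported internally",
              class = "partsurv_config_error")
  conversions <- character(0)

  config$seed <- as.integer(config$seed %||% 1L)
  config$cohort$start_age <- config$cohort$start_age %||% 60
  config$cohort$prop_female <- config$cohort$prop_female %||% 0.40
  eng <- config$engine %||% list()
  eng$cycle_length <- eng$cycle_length %||% (1 / 52)
  eng$horizon <- eng$horizon %||% 40
  eng$discount_qaly <- eng$discount_qaly %||% 0.035
  eng$discount_cost <- eng$discount_cost %||% 0.035
  for (r in c(eng$discount_qaly, eng$discount_cost))
    assert_that(is_number(r) && r >= 0 && r < 1,
                "engine: discount rates must lie in [0, 1)",
                class = "partsurv_config_error")
  assert_that(eng$cycle_length > 0 && eng$cycle_length <= eng$horizon,
              "engine: cycle_length must be positive and <= horizon",
              class = "partsurv_config_error")
  config$engine <- eng

  config$fit$criterion <- match.arg(config$fit$criterion %||% "aic",
                                    c("aic", "bic"))
  if (!is.null(config$fit$preferred_shape))
    assert_that(config$fit$preferred_shape %in%
                  c("increasing", "decreasing", "constant", "unimodal",
                    "bathtub-like"),
                "fit: unknown preferred_shape", class = "partsurv_config_error")
  else config$fit["preferred_shape"] <- list(NULL)

  u <- config$utilities
  assert_that(!is.null(u$pf) && !is.null(u$pd), "utilities: pf and pd required",
              class = "partsurv_config_error")
  assert_that(u$pf >= 0 && u$pf <= 1 && u$pd >= 0 && u$pd <= 1,
              "utilities must lie in [0, 1]", class = "partsurv_config_error")
  config$utilities$age_decrement_per_year <- u$age_decrement_per_year %||% 0

  costs <- config$costs
  assert_that(!is.null(costs), "costs block required",
              class = "partsurv_config_error")
  if (!is.null(costs$tender_prices)) {
    tp <- as.data.frame(do.call(rbind, lapply(
      if (is.data.frame(costs$tender_prices))
        split(costs$tender_prices, seq_len(nrow(costs$tender_prices)))
      else costs$tender_prices,
      function(x) data.frame(price = x$price, share = x$share))))
    assert_that(abs(sum(tp$share) - 1) <= 1e-9,
                "costs: tender_prices market shares must sum to 1 (got ",
                signif(sum(tp$share), 6), ")",
                class = "partsurv_config_error")
    config$costs$tender_prices <- tp
  }
  config$costs$price_statistic <- match.arg(costs$price_statistic %||% "mean",
                                            c("mean", "median"))
  config$costs$vial_sharing <- isTRUE(costs$vial_sharing)

  if (identical(config$ttd_unit %||% "years", "months")) {
    config$ttd <- lapply(config$ttd, function(x)
      if (is.numeric(x)) x / 12 else x)
    config$ttd_unit <- "years"
    conversions <- c(conversions, "ttd: months -> years (/12)")
  }

  sv <- config$severity %||% list()
  config$severity <- severity_config(
    prop_12 = sv$prop_12 %||% 0.85, abs_12 = sv$abs_12 %||% 12,
    prop_17 = sv$prop_17 %||% 0.95, abs_17 = sv$abs_17 %||% 18)

  if (!is.null(config$genpop$life_table))
    config$genpop$life_table <- as.data.frame(config$genpop$life_table)
  config$subsequent_qaly_addition <- config$subsequent_qaly_addition %||% 0
  config$thresholds <- config$thresholds %||% c(20000, 30000)
  config$scenarios <- config$scenarios %||% "base"

  psa <- config$psa %||% list()
  psa$n_draws <- psa$n_draws %||% 500
  psa$se_frac <- psa$se_frac %||% 0.10
  psa$sample_survival <- psa$sample_survival %||% TRUE
  psa$sample_price <- psa$sample_price %||% FALSE
  psa$vcov_scale <- psa$vcov_scale %||% 1
  config$psa <- psa

  structure(config, unit_conversions = conversions,
            class = c("pipeline_config", "list"))
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads a structured key-value file, validates it with [validate_config()],
#' and checks that any referenced evidence files exist (relative paths are
#' resolved against the config file's directory).
#'
#' @param path path to a YAML configuration file.
#' @return a validated `pipeline_config`.
#' @export
load_config <- function(path) {
  assert_that(file.exists(path), "config file not found: ", path,
              class = "partsurv_config_error")
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$genpop$life_table) && is.character(raw$genpop$life_table)) {
    lt_path <- file.path(dirname(path), raw$genpop$life_table)
    assert_that(file.exists(lt_path), "genpop: life_table file not found: ",
                lt_path, class = "partsurv_config_error")
    raw$genpop$life_table <- utils::read.delim(lt_path)
  }
  cfg <- validate_config(raw)
  if (!is.null(cfg$evidence)) {
    for (ev in cfg$evidence) {
      f <- file.path(dirname(path), ev$path)
      assert_that(file.exists(f), "evidence file not found: ", f,
                  class = "partsurv_config_error")
    }
  }
  cfg
}

# stable short hash of the config for provenance stamps in outputs
config_hash <- function(config) {
  txt <- paste(deparse(config[sort(names(config))]), collapse = "\n")
  # polynomial rolling hash over the serialised text (hex, 8 chars)
  h <- 0
  for (cp in utf8ToInt(txt)) h <- (h * 31 + cp) %% 2^28
  sprintf("%07x", h)
}
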