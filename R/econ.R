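#' ICER and incremental net monetary benefit
#'
#' `ICER = dCost / dQALY` with dominance handling; severity-weighted
#' `iNMB(lambda) = lambda * (w * dQALY) - dCost` at each threshold.
#'
#' @param increments list (or `comparison_result`) with `d_cost`, `d_qalys`
#'   and optionally `d_ly`.
#' @param thresholds willingness-to-pay thresholds, GBP per QALY.
#' @param severity_weight QALY weight (1.0, 1.2 or 1.7 under the modifier
#'   scheme; any positive value is accepted).
#' @return object of class `econ_result`: increments, `icer` (number or a
#'   dominance tag `"dominant"` / `"dominated"` / `"undefined"`), `inmb`
#'   (named by threshold) and the weight applied.
#' @export
icer <- function(increments, thresholds = c(20000, 30000),
                 severity_weight = 1.0) {
  dc <- increments$d_cost
  dq <- increments$d_qalys
  assert_that(is_number(dc) && is_number(dq),
              "increments must contain finite d_cost and d_qalys",
              class = "partsurv_parameter_error")
  assert_that(is_number(severity_weight) && severity_weight > 0,
              "severity_weight must be positive",
              class = "partsurv_parameter_error")
  icer_val <- if (dq > 0 && dc <= 0) "dominant"
    else if (dq < 0 && dc >= 0) "dominated"
    else if (dq == 0) "undefined"
    else dc / dq
  inmb <- setNames(thresholds * (severity_weight * dq) - dc,
                   paste0("at_", thresholds))
  structure(list(d_cost = dc, d_qalys = dq,
                 d_ly = increments$d_ly %||% NA_real_,
                 icer = icer_val, inmb = inmb,
                 severity_weight = severity_weight,
                 thresholds = thresholds),
            class = "econ_result")
}

#' @export
print.econ_result <- function(x, ...) {
  cat("<econ_result> dQALY =", signif(x$d_qalys, 4),
      " dCost =", signif(x$d_cost, 6),
      " weight =", x$severity_weight, "\n  ICER:",
      if (is.character(x$icer)) x$icer else
        paste0("GBP ", format(round(x$icer), big.mark = ","), "/QALY"), "\n")
  for (i in seq_along(x$inmb))
    cat("  iNMB ", names(x$inmb)[i], ": ", round(x$inmb[i]), "\n", sep = "")
  invisible(x)
}

#' Discounted QALY expectation of the matched general population
#'
#' Life-table product-sum: survival to each year of age from the cohort's
#' start age (product of `1 - qx`), multiplied by the age utility norm and the
#' discount factor, using a half-year convention (deaths mid-year; utility and
#' discounting evaluated at mid-year).
#'
#' @param start_age cohort age at entry.
#' @param life_table data frame `age`, `qx` (annual death probability),
#'   covering `start_age` through its last age (beyond which survivors are
#'   extinguished).
#' @param utility_norms function of age returning the general-population
#'   utility norm, or a single number.
#' @param discount_rate annual discount rate.
#' @param sex_mix unused placeholder for a sex-specific life table supplied as
#'   a pre-mixed `qx`; kept so callers can document the mix used.
#' @return discounted QALYs.
#' @export
general_population_qalys <- function(start_age, life_table, utility_norms = 1,
                                     discount_rate = 0.035, sex_mix = NULL) {
  ages <- seq(floor(start_age), max(life_table$age))
  qx <- life_table$qx[match(ages, life_table$age)]
  assert_that(!anyNA(qx), "life table missing ages ",
              paste(ages[is.na(qx)][1], "..."),
              class = "partsurv_config_error")
  ufun <- if (is.function(utility_norms)) utility_norms
          else function(a) rep(utility_norms, length(a))
  s_start <- cumprod(c(1, (1 - qx)[-length(qx)]))  # alive at start of year k
  s_mid <- s_start * (1 - qx / 2)
  yrs <- seq_along(ages) - 1
  sum(s_mid * ufun(ages + 0.5) * (1 + discount_rate)^(-(yrs + 0.5)))
}

#' Severity-modifier threshold scheme
#'
#' Default thresholds follow the NICE severity-modifier scheme: weight 1.2
#' when the proportional shortfall reaches 0.85 or the absolute shortfall
#' reaches 12 QALYs; weight 1.7 at 0.95 or 18 QALYs.
#'
#' @param prop_12,abs_12 thresholds for weight 1.2.
#' @param prop_17,abs_17 thresholds for weight 1.7.
#' @return a `severity_config`.
#' @export
severity_config <- function(prop_12 = 0.85, abs_12 = 12,
                            prop_17 = 0.95, abs_17 = 18) {
  structure(list(prop_12 = prop_12, abs_12 = abs_12,
                 prop_17 = prop_17, abs_17 = abs_17),
            class = "severity_config")
}

#' QALY shortfall and severity-modifier weight
#'
#' Adds the configured subsequent-treatment QALY contribution to the
#' standard-care QALYs *before* computing the shortfall (the correction that
#' guards against overstating severity when later treatment lines are excluded
#' from the model; it deliberately tolerates some double counting and is used
#' only here, never in the ICER increments). Absolute shortfall is the general
#' population's discounted QALY expectation minus adjusted standard-care
#' QALYs; proportional shortfall divides that by the general-population
#' expectation.
#'
#' @param soc_qalys discounted QALYs of the standard-care arm from the model.
#' @param subsequent_addition QALYs added for subsequent treatment lines.
#' @param genpop_qalys from [general_population_qalys()]; must be positive.
#' @param config a [severity_config()].
#' @return object of class `shortfall_result`: `genpop_qalys`,
#'   `soc_qalys_adjusted`, `absolute_shortfall`, `proportional_shortfall`,
#'   `weight`.
#' @export
qaly_shortfall <- function(soc_qalys, subsequent_addition = 0, genpop_qalys,
                           config = severity_config()) {
  assert_that(is_number(genpop_qalys) && genpop_qalys > 0,
              "genpop_qalys must be positive", class = "partsurv_config_error")
  adj <- soc_qalys + subsequent_addition
  assert_that(adj >= 0, "adjusted standard-care QALYs are negative",
              class = "partsurv_config_error")
  abs_sf <- genpop_qalys - adj
  prop_sf <- max(min(abs_sf / genpop_qalys, 1), 0)
  weight <- if (prop_sf >= config$prop_17 || abs_sf >= config$abs_17) 1.7
    else if (prop_sf >= config$prop_12 || abs_sf >= config$abs_12) 1.2
    else 1.0
  structure(list(genpop_qalys = genpop_qalys, soc_qalys_adjusted = adj,
                 absolute_shortfall = abs_sf,
                 proportional_shortfall = prop_sf, weight = weight),
            class = "shortfall_result")
}

#' @export
print.shortfall_result <- function(x, ...) {
  cat(sprintf(paste0("<shortfall_result> genpop %.2f QALYs, adjusted SoC %.2f",
                     " -> absolute %.2f, proportional %.2f, weight x%.1f\n"),
              x$genpop_qalys, x$soc_qalys_adjusted, x$absolute_shortfall,
              x$proportional_shortfall, x$weight))
  invisible(x)
}

#' Transfer a relative ICER difference across treatment lines
#'
#' When a comparison lacks direct evidence in one setting, its ICER is
#' inferred by assuming the relative difference between two first-line ICERs
#' carries over: `inferred = anchor * (first_line_b / first_line_a)`.
#'
#' @param first_line_a ICER of the anchored comparison in the evidence-rich
#'   setting (GBP/QALY, finite positive).
#' @param first_line_b ICER of the comparison to be transferred.
#' @param anchor ICER of the anchored comparison in the target setting.
#' @return inferred ICER (GBP/QALY).
#' @export
transfer_relative_icer <- function(first_line_a, first_line_b, anchor) {
  for (v in list(first_line_a, first_line_b, anchor))
    if (!is_number(v) || v <= 0)
      stop_partsurv("relative-ICER transfer needs finite positive ICERs ",
                    "(dominance tags cannot be transferred)",
                    class = "partsurv_transfer_error")
  anchor * (first_line_b / first_line_a)
}
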