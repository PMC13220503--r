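#' Step-function representation of a survival curve
#'
#' Right-continuous step function equal to 1 before the first knot, taking
#' `values[i]` on `[knots[i], knots[i+1])`.
#'
#' @param knots ordered times.
#' @param values survival values at/after each knot, non-increasing in [0,1].
#' @return object of class `step_function`.
#' @export
step_function <- function(knots, values) {
  assert_that(length(knots) == length(values), "knots/values length mismatch",
              class = "partsurv_invalid")
  assert_that(!is.unsorted(knots, strictly = TRUE),
              "knots must be strictly increasing", class = "partsurv_invalid")
  assert_that(all(values >= -1e-12 & values <= 1 + 1e-12) &&
                all(diff(values) <= 1e-12),
              "values must be non-increasing within [0, 1]",
              class = "partsurv_invalid")
  structure(list(knots = knots, values = pmin(pmax(values, 0), 1)),
            class = "step_function")
}

#' Evaluate a step function
#'
#' @param f a [step_function()].
#' @param t times at which to evaluate.
#' @return survival values; 1 for `t` before the first knot.
#' @export
eval_step <- function(f, t) {
  assert_that(inherits(f, "step_function"), "f must be a step_function",
              class = "partsurv_parameter_error")
  if (length(f$knots) == 0) return(rep(1, length(t)))
  idx <- findInterval(t, f$knots)
  ifelse(idx == 0, 1, f$values[pmax(idx, 1)])
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimate with Greenwood standard errors and a risk table at
#' the event times. Ties are handled by simultaneous multiplication, so the
#' curve drops only at event times.
#'
#' @param data a [survival_dataset()].
#' @return list of class `km_fit`: `step` (a [step_function()] dropping at
#'   event times), `table` (time, n.risk, n.event, n.censor, surv, std.err of
#'   survival by Greenwood's formula), and `n`.
#' @export
km_estimate <- function(data) {
  assert_that(inherits(data, "survival_dataset") && nrow(data) >= 1,
              "data must be a non-empty survival_dataset",
              class = "partsurv_parameter_error")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = as.data.frame(data), conf.type = "none")
  tab <- data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                    n_censor = sf$n.censor, surv = sf$surv,
                    std_err = sf$surv * sf$std.err)
  drops <- tab[tab$n_event > 0, , drop = FALSE]
  step <- if (nrow(drops)) step_function(drops$time, drops$surv)
          else step_function(max(data$time), 1)
  structure(list(step = step, table = tab, n = nrow(data)), class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat("<km_fit> n =", x$n, "with", sum(x$table$n_event), "events\n")
  invisible(x)
}

#' Piecewise-exponential empirical hazard
#'
#' Bins follow-up time and estimates a constant hazard per bin as events
#' divided by person-time at risk in the bin; bins containing no person-time
#' are omitted.
#'
#' @param data a [survival_dataset()].
#' @param bin_width bin width in years (default 0.25, i.e. 3 months).
#' @return a `hazard_curve`: data frame with `time` (bin midpoint), `hazard`
#'   (per year), `events`, `person_time`, and attribute `method`.
#' @export
piecewise_hazard <- function(data, bin_width = 0.25) {
  assert_that(is_number(bin_width) && bin_width > 0,
              "bin_width must be positive", class = "partsurv_parameter_error")
  tmax <- max(data$time)
  breaks <- seq(0, tmax + bin_width, by = bin_width)
  lower <- breaks[-length(breaks)]
  upper <- breaks[-1]
  events <- pt <- numeric(length(lower))
  for (i in seq_along(lower)) {
    at_risk_time <- pmin(data$time, upper[i]) - lower[i]
    pt[i] <- sum(pmax(at_risk_time, 0))
    events[i] <- sum(data$event == 1 & data$time > lower[i] &
                       data$time <= upper[i])
  }
  keep <- pt > 0
  out <- data.frame(time = (lower + upper)[keep] / 2,
                    hazard = events[keep] / pt[keep],
                    events = events[keep], person_time = pt[keep])
  structure(out, method = "piecewise_exponential",
            class = c("hazard_curve", "data.frame"))
}

#' Spline-smoothed empirical hazard
#'
#' Smooth hazard estimate obtained by Poisson regression of event counts on a
#' cubic B-spline basis in time, on fine bins with a log person-time offset;
#' the fitted hazard is therefore positive by construction. Interior knots are
#' placed at event-time quantiles.
#'
#' @param data a [survival_dataset()] with at least 10 events.
#' @param knot_count number of interior knots (default 3).
#' @param n_bins number of fine bins used for the Poisson likelihood.
#' @param n_grid number of output grid points.
#' @return a `hazard_curve` data frame (`time`, `hazard`).
#' @export
smoothed_hazard <- function(data, knot_count = 3, n_bins = 100, n_grid = 101) {
  n_events <- sum(data$event)
  if (n_events < 10)
    stop_partsurv("smoothed hazard needs at least 10 events (got ",
                  n_events, ")", class = "partsurv_estimation_error")
  tmax <- max(data$time)
  breaks <- seq(0, tmax, length.out = n_bins + 1)
  lower <- breaks[-length(breaks)]
  upper <- breaks[-1]
  ev <- pt <- numeric(length(lower))
  for (i in seq_along(lower)) {
    pt[i] <- sum(pmax(pmin(data$time, upper[i]) - lower[i], 0))
    ev[i] <- sum(data$event == 1 & data$time > lower[i] &
                   data$time <= upper[i])
  }
  mid <- (lower + upper) / 2
  keep <- pt > 0
  knots <- quantile(data$time[data$event == 1],
                    probs = seq_len(knot_count) / (knot_count + 1),
                    names = FALSE, type = 7)
  knots <- knots[knots > min(mid[keep]) & knots < max(mid[keep])]
  basis <- splines::bs(mid[keep], knots = unique(knots), degree = 3,
                       Boundary.knots = c(0, tmax))
  fit <- stats::glm(ev[keep] ~ basis, family = stats::poisson(),
                    offset = log(pt[keep]))
  grid <- seq(tmax / n_grid, tmax, length.out = n_grid)
  gbasis <- stats::predict(basis, pmin(grid, max(mid[keep])))
  eta <- cbind(1, gbasis) %*% stats::coef(fit)
  out <- data.frame(time = grid, hazard = as.numeric(exp(eta)))
  structure(out, method = "bspline_smoothed",
            class = c("hazard_curve", "data.frame"))
}
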