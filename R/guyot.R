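#' Reconstruct pseudo-individual patient data from a digitised KM curve
#'
#' Implements the interval algorithm of Guyot and colleagues: within each
#' numbers-at-risk interval, event and censoring counts are allocated so that
#' the running product-limit estimate tracks the digitised drops, and the
#' assumed number of censorings is adjusted iteratively until the implied
#' number at risk matches the next risk-table entry. When the total event
#' count is available, the final interval is calibrated so the reconstructed
#' events sum to it; when it is absent that calibration step is skipped and
#' the last-interval censoring count is extrapolated from the censoring rate
#' observed over the earlier intervals.
#'
#' Censorings within an interval are placed at evenly spaced times (an
#' algorithmic convention; it perturbs person-time slightly but not the KM
#' step heights). Non-monotone digitised coordinates are repaired by a running
#' minimum before reconstruction. Subjects still at risk at the end of
#' follow-up are emitted as censored at the last digitised time.
#'
#' @param curve a [digitized_curve()]; the risk table must start at time 0.
#' @param total_events optional override of the curve's recorded event total;
#'   `NULL` skips the final calibration.
#' @param arm,endpoint labels for the output dataset.
#' @return a [survival_dataset()] whose KM estimate approximates the input
#'   coordinates.
#' @export
reconstruct_ipd <- function(curve, total_events = curve$total_events,
                            arm = "arm", endpoint = "OS") {
  assert_that(inherits(curve, "digitized_curve"), "curve must be a digitized_curve",
              class = "partsurv_parameter_error")
  tS <- curve$coords$time
  S <- cummin(pmin(pmax(curve$coords$surv, 0), 1))
  S[1] <- 1
  trisk <- curve$risk_table$time
  nrisk <- curve$risk_table$n_risk
  assert_that(trisk[1] == 0, "risk table must start at time 0",
              class = "partsurv_reconstruction_error")
  tmax <- max(tS)
  keep <- trisk <= tmax
  trisk <- trisk[keep]
  nrisk <- nrisk[keep]
  M <- length(trisk)
  assert_that(M >= 1, "risk table has no usable interval",
              class = "partsurv_reconstruction_error")
  # intervals between consecutive risk times carry an at-risk target; an
  # extra target-free tail interval exists when the curve extends beyond the
  # last risk-table time
  has_tail <- trisk[M] < tmax
  n_int <- if (has_tail) M else M - 1
  assert_that(n_int >= 1, "risk table has no usable interval",
              class = "partsurv_reconstruction_error")

  clicks <- which(tS > 0)                      # candidate drop coordinates
  intv <- findInterval(tS[clicks] - 1e-12, trisk)
  upper_t <- c(trisk[-1], tmax)                # interval i = (trisk[i], upper_t[i]]

  # run one interval for a proposed censoring count; returns exit state.
  # censorings never exceed the people actually at risk: requested censor
  # times beyond the available risk set are discarded, not emitted.
  solve_interval <- function(nc, kset, a, b, n_entry, S_run) {
    cen_prop <- if (nc > 0) a + seq_len(nc) * (b - a) / (nc + 1) else numeric(0)
    cen_t <- numeric(0)
    d <- numeric(length(kset))
    n_now <- n_entry
    seg_lo <- a
    take_censors <- function(upper) {
      seg <- cen_prop[cen_prop >= seg_lo & cen_prop < upper]
      seg <- seg[seq_len(min(length(seg), n_now))]
      cen_t <<- c(cen_t, seg)
      n_now <<- n_now - length(seg)
    }
    for (j in seq_along(kset)) {
      k <- kset[j]
      take_censors(tS[k])
      dj <- 0
      if (n_now > 0 && S_run > 0) {
        dj <- round(n_now * (1 - S[k] / S_run))
        dj <- max(0, min(dj, n_now))
        if (dj > 0) S_run <- S_run * (1 - dj / n_now)
      }
      n_now <- n_now - dj
      d[j] <- dj
      seg_lo <- tS[k]
    }
    take_censors(Inf)
    list(n_exit = n_now, d = d, S_run = S_run, cen_t = cen_t)
  }

  ev_times <- cen_times <- numeric(0)
  n_entry <- nrisk[1]
  S_run <- 1
  nc_hist <- numeric(n_int)

  for (i in seq_len(n_int)) {
    kset <- clicks[intv == i]
    a <- trisk[i]
    b <- upper_t[i]
    last_interval <- has_tail && (i == n_int)
    S_end <- if (length(kset)) S[kset[length(kset)]] else S_run

    if (!last_interval) {
      target <- nrisk[i + 1]
      # arithmetic feasibility: even with no censoring, can we keep `target` at risk?
      min_events <- if (S_run > 0)
        max(0, round(n_entry * (1 - S_end / S_run))) else 0
      if (n_entry - min_events < target - max(2, 0.02 * target))
        stop_partsurv("risk table infeasible in interval ", i,
                      ": at most ", n_entry - min_events,
                      " can remain at risk but ", target, " reported",
                      class = "partsurv_reconstruction_error")
      nc <- if (S_run > 0) round(n_entry * S_end / S_run - target) else 0
      nc <- max(0, nc)
      tried <- integer(0)
      repeat {
        res <- solve_interval(nc, kset, a, b, n_entry, S_run)
        gap <- res$n_exit - target
        if (gap == 0) break
        new_nc <- max(0, nc + gap)
        if (new_nc == nc || new_nc %in% tried || length(tried) > 100) break
        tried <- c(tried, nc)
        nc <- new_nc
      }
      if (res$n_exit < target) target <- res$n_exit  # absorb rounding slack
      nrisk[i + 1] <- target
    } else if (!is.null(total_events)) {
      prior_events <- length(ev_times)
      nc <- 0
      tried <- integer(0)
      repeat {
        res <- solve_interval(nc, kset, a, b, n_entry, S_run)
        gap <- (prior_events + sum(res$d)) - total_events
        if (gap == 0) break
        new_nc <- min(max(0, nc + gap), n_entry)
        if (new_nc == nc || new_nc %in% tried || length(tried) > 100) break
        tried <- c(tried, nc)
        nc <- new_nc
      }
    } else {
      # no reported total: extrapolate the earlier intervals' censoring rate
      prev_span <- max(trisk[M] - trisk[1], .Machine$double.eps)
      nc <- min(round(sum(nc_hist[seq_len(n_int - 1)]) * (b - a) / prev_span),
                n_entry)
      nc <- max(0, nc)
      res <- solve_interval(nc, kset, a, b, n_entry, S_run)
    }

    nc_hist[i] <- length(res$cen_t)
    ev_times <- c(ev_times, rep(tS[kset], res$d))
    cen_times <- c(cen_times, res$cen_t)
    n_entry <- res$n_exit
    S_run <- res$S_run
  }

  if (n_entry > 0) cen_times <- c(cen_times, rep(tmax, n_entry))
  assert_that(length(ev_times) + length(cen_times) > 0,
              "reconstruction produced no records",
              class = "partsurv_reconstruction_error")
  survival_dataset(
    time = pmax(c(ev_times, cen_times), 1e-9),
    event = c(rep(1L, length(ev_times)), rep(0L, length(cen_times))),
    arm = arm, endpoint = endpoint
  )
}
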