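#' Data-generating model for one trial arm
#'
#' @param family one of [surv_families()].
#' @param params named parameter vector (natural scale).
#' @param label arm identifier.
#' @return an object of class `true_arm_model`.
#' @export
true_arm_model <- function(family, params, label = "arm") {
  params <- check_family_params(family, params)
  structure(list(family = family, params = params, label = label),
            class = "true_arm_model")
}

#' Censoring mechanism for simulated trials
#'
#' Administrative censoring at a fixed follow-up time plus exponential
#' random dropout.
#'
#' @param admin_time administrative censoring time (years, > 0).
#' @param dropout_rate exponential dropout rate per year (>= 0).
#' @return an object of class `censoring_spec`.
#' @export
censoring_spec <- function(admin_time, dropout_rate = 0) {
  assert_that(is_number(admin_time) && admin_time > 0,
              "admin_time must be a positive number",
              class = "partsurv_parameter_error")
  assert_that(is_number(dropout_rate) && dropout_rate >= 0,
              "dropout_rate must be non-negative",
              class = "partsurv_parameter_error")
  structure(list(admin_time = admin_time, dropout_rate = dropout_rate),
            class = "censoring_spec")
}

# event times via inverse-survival transform of uniforms; shared uniforms give
# the comonotone coupling used for linked endpoints
.sim_times <- function(model, u) {
  t <- family_inv_survival(model$family, model$params, u)
  pmax(t, 1e-12)
}

.sim_dropout <- function(censoring, n) {
  if (censoring$dropout_rate > 0) rexp(n, censoring$dropout_rate) else rep(Inf, n)
}

#' Simulate one right-censored trial arm
#'
#' Event times are drawn by inverse-survival transform; observed time is the
#' minimum of event time, dropout time and the administrative cut-off, with
#' `event = 1` iff the event came first.
#'
#' @param model a [true_arm_model()].
#' @param censoring a [censoring_spec()].
#' @param n number of subjects.
#' @param seed integer seed (identical seeds give identical datasets).
#' @param endpoint endpoint label for the output dataset.
#' @return a [survival_dataset()].
#' @export
simulate_arm <- function(model, censoring, n, seed, endpoint = "OS") {
  assert_that(inherits(model, "true_arm_model"), "model must be a true_arm_model",
              class = "partsurv_parameter_error")
  assert_that(is_number(n) && n >= 1, "n must be >= 1",
              class = "partsurv_parameter_error")
  with_seed(seed, {
    u <- runif(n)
    t_event <- .sim_times(model, u)
    t_drop <- .sim_dropout(censoring, n)
    t_cens <- pmin(t_drop, censoring$admin_time)
    obs <- pmin(t_event, t_cens)
    survival_dataset(obs, as.integer(t_event <= t_cens),
                     arm = model$label, endpoint = endpoint)
  })
}

#' Simulate per-subject-linked OS and PFS for one arm
#'
#' OS and PFS event times are generated from a shared uniform draw per subject
#' (comonotone coupling), so that whenever the marginal PFS survival lies below
#' the marginal OS survival, every subject's PFS time is at most their OS time.
#' The two endpoints share the same censoring times per subject.
#'
#' @param os_model,pfs_model [true_arm_model()] objects for OS and PFS.
#' @param censoring a [censoring_spec()].
#' @param n number of subjects.
#' @param seed integer seed.
#' @param check_grid number of grid points on `[0, admin_time]` used to verify
#'   that the PFS marginal never exceeds the OS marginal.
#' @return list with elements `os` and `pfs`, both [survival_dataset()]s.
#' @export
simulate_linked_endpoints <- function(os_model, pfs_model, censoring, n, seed,
                                      check_grid = 201) {
  grid <- seq(0, censoring$admin_time, length.out = check_grid)
  s_os <- family_survival_at(os_model$family, os_model$params, grid)
  s_pfs <- family_survival_at(pfs_model$family, pfs_model$params, grid)
  bad <- which(s_pfs > s_os + 1e-9)
  if (length(bad))
    stop_partsurv("PFS marginal survival exceeds OS marginal survival ",
                  "(first at t = ", signif(grid[bad[1]], 4), ")",
                  class = "partsurv_consistency_error")
  with_seed(seed, {
    u <- runif(n)
    t_os <- .sim_times(os_model, u)
    t_pfs <- pmin(.sim_times(pfs_model, u), t_os)
    t_drop <- .sim_dropout(censoring, n)
    t_cens <- pmin(t_drop, censoring$admin_time)
    list(
      os = survival_dataset(pmin(t_os, t_cens), as.integer(t_os <= t_cens),
                            arm = os_model$label, endpoint = "OS"),
      pfs = survival_dataset(pmin(t_pfs, t_cens), as.integer(t_pfs <= t_cens),
                             arm = pfs_model$label, endpoint = "PFS")
    )
  })
}

#' Simulate the digitisation of a published KM figure
#'
#' Computes the Kaplan-Meier estimate of a dataset, samples its value on a
#' regular time grid (emulating coordinate extraction from a figure at finite
#' resolution), and tabulates numbers at risk at multiples of
#' `risk_table_interval`. Optional uniform jitter emulates extraction error;
#' jittered coordinates are made monotone again by a running minimum.
#'
#' @param dataset a [survival_dataset()].
#' @param grid_points number of grid points (>= 2) spanning `[0, max(time)]`.
#' @param risk_table_interval spacing of the risk table (years).
#' @param jitter half-width of uniform noise added to survival coordinates
#'   (default 0 = noiseless).
#' @param seed seed for the jitter draw (only used when `jitter > 0`).
#' @return a [digitized_curve()] with `total_events` filled in.
#' @export
digitize <- function(dataset, grid_points, risk_table_interval,
                     jitter = 0, seed = 1) {
  assert_that(inherits(dataset, "survival_dataset") && nrow(dataset) >= 1,
              "dataset must be a non-empty survival_dataset",
              class = "partsurv_parameter_error")
  assert_that(is_number(grid_points) && grid_points >= 2,
              "grid_points must be at least 2",
              class = "partsurv_parameter_error")
  assert_that(is_number(risk_table_interval) && risk_table_interval > 0,
              "risk_table_interval must be positive",
              class = "partsurv_parameter_error")
  km <- km_estimate(dataset)
  tmax <- max(dataset$time)
  dx <- tmax / (round(grid_points) - 1)
  # drop locations snap to the nearest grid position, as when clicking the
  # corners of the published steps at finite figure resolution
  snapped <- pmin(pmax(round(km$step$knots / dx) * dx, dx), tmax)
  grid <- unique(snapped)
  s <- vapply(grid, function(g) min(km$step$values[snapped == g]), numeric(1))
  grid <- c(0, grid)
  s <- c(1, s)
  if (grid[length(grid)] < tmax) {
    grid <- c(grid, tmax)
    s <- c(s, s[length(s)])
  }
  if (jitter > 0) {
    s <- with_seed(seed, s + runif(length(s), -jitter, jitter))
    s[1] <- 1
    s <- cummin(pmin(pmax(s, 0), 1))  # isotonic repair of extraction noise
  }
  rt_times <- seq(0, tmax, by = risk_table_interval)
  n_risk <- vapply(rt_times, function(tt) sum(dataset$time > tt), numeric(1))
  n_risk[1] <- nrow(dataset)
  keep <- c(TRUE, n_risk[-1] >= 0)
  digitized_curve(
    coords = data.frame(time = grid, surv = s),
    risk_table = data.frame(time = rt_times[keep], n_risk = n_risk[keep]),
    total_events = sum(dataset$event)
  )
}
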