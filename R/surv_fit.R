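#' Fit one parametric survival family by censored maximum likelihood
#'
#' Maximises the right-censored log-likelihood
#' \eqn{\sum_{events} \log f(t) + \sum_{censored} \log S(t)} for one of the
#' seven families, via `flexsurv::flexsurvreg` (which uses the stable log-time
#' generalised-gamma parameterisation and estimates positive parameters on the
#' log scale). AIC and BIC are recomputed from the log-likelihood so the
#' identities `AIC = 2k - 2 logL` and `BIC = k log(n) - 2 logL` hold exactly.
#'
#' @param data a [survival_dataset()] with at least one event.
#' @param family one of [surv_families()].
#' @return object of class `parametric_model`: family, `params` (natural
#'   scale), `params_t` (estimation scale: log for positive-constrained
#'   parameters), `vcov` (estimation scale), `loglik`, `aic`, `bic`, `n`,
#'   `n_events`, `converged`.
#' @export
fit_parametric <- function(data, family) {
  info <- family_info(family)
  assert_that(inherits(data, "survival_dataset"), "data must be a survival_dataset",
              class = "partsurv_parameter_error")
  if (sum(data$event) < 1)
    stop_partsurv("cannot fit ", family, ": data contain no events",
                  class = "partsurv_estimation_error")
  df <- as.data.frame(data)
  fit <- try(suppressWarnings(
    flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = df,
                          dist = info$dist)), silent = TRUE)
  if (inherits(fit, "try-error") || any(!is.finite(fit$res[, "est"])) ||
      !is.finite(fit$loglik)) {
    return(structure(list(family = family, converged = FALSE,
                          n = nrow(df), n_events = sum(df$event)),
                     class = "parametric_model"))
  }
  params <- setNames(fit$res[, "est"], rownames(fit$res))[info$pars]
  params_t <- setNames(fit$res.t[, "est"], rownames(fit$res.t))[info$pars]
  vcov <- as.matrix(fit$cov)
  dimnames(vcov) <- list(rownames(fit$res.t), rownames(fit$res.t))
  k <- length(info$pars)
  ll <- fit$loglik
  structure(list(
    family = family,
    params = params,
    params_t = params_t,
    vcov = vcov[info$pars, info$pars, drop = FALSE],
    loglik = ll,
    aic = 2 * k - 2 * ll,
    bic = k * log(nrow(df)) - 2 * ll,
    n = nrow(df),
    n_events = sum(df$event),
    converged = TRUE
  ), class = "parametric_model")
}

#' @export
print.parametric_model <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<parametric_model>", x$family, "(did not converge)\n")
    return(invisible(x))
  }
  cat("<parametric_model> ", x$family, ": ",
      paste(names(x$params), "=", signif(x$params, 4), collapse = ", "),
      "\n  logLik ", signif(x$loglik, 6), "  AIC ", signif(x$aic, 6),
      "  BIC ", signif(x$bic, 6), "  (n = ", x$n, ", events = ", x$n_events,
      ")\n", sep = "")
  invisible(x)
}

#' Survival-function object from a fitted model
#'
#' @param model a converged `parametric_model`.
#' @return a [surv_fn()].
#' @export
surv_fn_model <- function(model) {
  assert_that(inherits(model, "parametric_model") && isTRUE(model$converged),
              "model must be a converged parametric_model",
              class = "partsurv_parameter_error")
  surv_fn_family(model$family, model$params)
}

#' Classify the hazard shape of a fitted model
#'
#' Evaluates the analytic hazard on a dense grid over `(0, horizon]` and
#' counts tolerance-guarded sign changes of its finite differences.
#'
#' @param model a converged `parametric_model` (or a [surv_fn()] with a hazard).
#' @param horizon upper end of the classification window (years).
#' @param n_grid grid density.
#' @param rel_tol differences smaller than `rel_tol * max(hazard)` count as flat.
#' @return one of `"increasing"`, `"decreasing"`, `"constant"`, `"unimodal"`,
#'   `"bathtub-like"`.
#' @export
classify_hazard_shape <- function(model, horizon, n_grid = 512,
                                  rel_tol = 1e-4) {
  if (inherits(model, "parametric_model")) {
    assert_that(isTRUE(model$converged), "model did not converge",
                class = "partsurv_parameter_error")
    hfun <- function(t) family_hazard_at(model$family, model$params, t)
    sfun <- function(t) family_survival_at(model$family, model$params, t)
  } else {
    hfun <- model$hazard
    sfun <- model$surv
  }
  grid <- seq(horizon / n_grid, horizon, length.out = n_grid)
  # classify only where the survival function has not numerically vanished:
  # beyond that point density/hazard evaluations are pure underflow noise
  grid <- grid[sfun(grid) > 1e-10]
  if (length(grid) < 3) grid <- seq(horizon / n_grid, horizon / 10,
                                    length.out = 64)
  h <- hfun(grid)
  ok <- is.finite(h)
  h <- h[ok]
  d <- diff(h)
  tol <- rel_tol * max(abs(h)) + 1e-300
  s <- sign(d) * (abs(d) > tol)
  pattern <- rle(s[s != 0])$values
  if (length(pattern) == 0) return("constant")
  if (all(pattern == 1)) return("increasing")
  if (all(pattern == -1)) return("decreasing")
  if (identical(pattern, c(1, -1))) return("unimodal")
  if (identical(pattern, c(-1, 1))) return("bathtub-like")
  if (pattern[1] == 1) "unimodal" else "bathtub-like"
}

#' Fit and rank all seven families
#'
#' Fits every family, tags hazard shapes, and proposes a base-case family
#' (best information criterion among models whose hazard shape matches the
#' clinically asserted shape, falling back to all converged models when none
#' matches) and a sensitivity family (the converged model whose extrapolated
#' survival at the horizon differs most from the base case).
#'
#' @param data a [survival_dataset()].
#' @param horizon extrapolation horizon (years) used for shape tags and the
#'   sensitivity-family rule.
#' @param preferred_shape clinically asserted hazard shape (default
#'   `"increasing"`); `NULL` disables the shape filter.
#' @param criterion `"aic"` or `"bic"`.
#' @return object of class `model_ranking`: `fits` (named list), `table`
#'   (one row per family, sorted by the criterion with non-converged fits
#'   last), `base_family`, `sensitivity_family`.
#' @export
fit_all <- function(data, horizon = 40, preferred_shape = "increasing",
                    criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  fits <- lapply(setNames(nm = surv_families()),
                 function(f) fit_parametric(data, f))
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (sum(conv) < 2)
    stop_partsurv("fewer than 2 families converged; cannot rank",
                  class = "partsurv_ranking_error")
  shape <- vapply(names(fits), function(f) {
    if (conv[[f]]) classify_hazard_shape(fits[[f]], horizon) else NA_character_
  }, character(1))
  tab <- data.frame(
    family = names(fits),
    converged = conv,
    loglik = vapply(fits, function(f) f$loglik %||% NA_real_, numeric(1)),
    aic = vapply(fits, function(f) f$aic %||% NA_real_, numeric(1)),
    bic = vapply(fits, function(f) f$bic %||% NA_real_, numeric(1)),
    hazard_shape = shape,
    row.names = NULL
  )
  crit <- tab[[criterion]]
  tab <- tab[order(!tab$converged, crit), ]
  sel <- select_families(list(fits), horizon = horizon,
                         preferred_shape = preferred_shape,
                         criterion = criterion, shapes = list(shape))
  structure(list(fits = fits, table = tab,
                 base_family = sel$base, sensitivity_family = sel$sensitivity,
                 criterion = criterion),
            class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, ...) {
  cat("<model_ranking> base:", x$base_family,
      " sensitivity:", x$sensitivity_family, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Joint family selection across arms
#'
#' Codifies the selection policy: the same family must be used in every arm;
#' the base case is the family with the best summed information criterion
#' among families that converged in all arms and whose hazard-shape tag
#' matches the asserted shape in all arms (falling back to all jointly
#' converged families when none matches); the sensitivity family is the
#' jointly converged family whose modelled survival at the horizon differs
#' most (summed over arms) from the base case.
#'
#' @param fits_by_arm list (one element per arm) of named lists of
#'   `parametric_model` fits.
#' @param horizon horizon (years) for the sensitivity rule.
#' @param preferred_shape asserted hazard shape or `NULL`.
#' @param criterion `"aic"` or `"bic"`.
#' @param shapes optional precomputed shape tags (list of named vectors).
#' @return list with `base` and `sensitivity` family names.
#' @export
select_families <- function(fits_by_arm, horizon = 40,
                            preferred_shape = "increasing",
                            criterion = "aic", shapes = NULL) {
  fams <- surv_families()
  conv <- vapply(fams, function(f)
    all(vapply(fits_by_arm, function(a) isTRUE(a[[f]]$converged), logical(1))),
    logical(1))
  assert_that(sum(conv) >= 2, "fewer than 2 families converged in all arms",
              class = "partsurv_ranking_error")
  if (is.null(shapes))
    shapes <- lapply(fits_by_arm, function(a)
      vapply(fams, function(f)
        if (isTRUE(a[[f]]$converged)) classify_hazard_shape(a[[f]], horizon)
        else NA_character_, character(1)))
  crit_sum <- vapply(fams, function(f) {
    if (!conv[[f]]) return(Inf)
    sum(vapply(fits_by_arm, function(a) a[[f]][[criterion]], numeric(1)))
  }, numeric(1))
  shape_ok <- vapply(fams, function(f) {
    if (!conv[[f]]) return(FALSE)
    if (is.null(preferred_shape)) return(TRUE)
    all(vapply(shapes, function(s) identical(s[[f]], preferred_shape),
               logical(1)))
  }, logical(1))
  pool <- if (any(shape_ok)) fams[shape_ok] else fams[conv]
  base <- pool[which.min(crit_sum[pool])]
  s_h <- function(f) vapply(fits_by_arm, function(a)
    family_survival_at(f, a[[f]]$params, horizon), numeric(1))
  base_s <- s_h(base)
  cand <- setdiff(fams[conv], base)
  dist <- vapply(cand, function(f) sum(abs(s_h(f) - base_s)), numeric(1))
  list(base = base, sensitivity = if (length(cand)) cand[which.max(dist)]
       else NA_character_)
}

#' Proportional-hazards transform of a survival curve
#'
#' Returns the curve with survival \eqn{S(t)^{hr}}, used to construct an
#' intervention curve from a comparator fit and a meta-analytic hazard ratio.
#'
#' @param base a `parametric_model` or [surv_fn()].
#' @param hr hazard ratio (> 0); values below 1 raise survival.
#' @return a [surv_fn()].
#' @export
apply_hazard_ratio <- function(base, hr) {
  assert_that(is_number(hr) && hr > 0, "hr must be a positive number",
              class = "partsurv_parameter_error")
  base_fn <- if (inherits(base, "parametric_model")) surv_fn_model(base)
             else base
  surv_fn(
    surv = function(t) eval_surv(base_fn, t) ^ hr,
    hazard = if (!is.null(base_fn$hazard))
      function(t) hr * base_fn$hazard(t),
    label = paste0(base_fn$label, " ^ HR ", signif(hr, 4))
  )
}

#' Discounted restricted mean survival by adaptive quadrature
#'
#' \eqn{\int_0^T (1+r)^{-t} S(t)\,dt}, the continuous-time oracle against
#' which the cycle-based engine is checked.
#'
#' @param surv a [surv_fn()].
#' @param horizon upper limit T (years).
#' @param discount_rate annual discount rate r (>= 0).
#' @return restricted mean in (discounted) years.
#' @export
restricted_mean <- function(surv, horizon, discount_rate = 0) {
  assert_that(is_number(horizon) && horizon > 0, "horizon must be positive",
              class = "partsurv_parameter_error")
  assert_that(is_number(discount_rate) && discount_rate >= 0,
              "discount_rate must be non-negative",
              class = "partsurv_parameter_error")
  integrand <- function(t) eval_surv(surv, t) * (1 + discount_rate)^(-t)
  # split the range to keep the adaptive rule honest over long horizons
  cuts <- unique(c(seq(0, horizon, length.out = 9), horizon))
  total <- 0
  for (i in seq_len(length(cuts) - 1)) {
    total <- total + integrate(integrand, cuts[i], cuts[i + 1],
                               rel.tol = 1e-9, subdivisions = 500L)$value
  }
  total
}
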