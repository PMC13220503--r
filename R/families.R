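#' The seven parametric survival families
#'
#' The distribution menu used throughout the package: exponential, Weibull,
#' Gompertz, log-normal, log-logistic, gamma and generalised gamma. The
#' generalised gamma uses the stable log-time (Prentice) parameterisation
#' `(mu, sigma, Q)`, which nests the Weibull (`Q = 1`), log-normal (`Q = 0`)
#' and gamma (`Q = sigma`) families.
#'
#' @return character vector of the seven family names.
#' @export
surv_families <- function() {
  c("exponential", "weibull", "gompertz", "lognormal", "loglogistic",
    "gamma", "gengamma")
}

# family name -> flexsurv/stats distribution suffix and parameter names
.family_table <- list(
  exponential = list(dist = "exp",      pars = "rate",
                     positive = "rate"),
  weibull     = list(dist = "weibull",  pars = c("shape", "scale"),
                     positive = c("shape", "scale")),
  gompertz    = list(dist = "gompertz", pars = c("shape", "rate"),
                     positive = "rate"),
  lognormal   = list(dist = "lnorm",    pars = c("meanlog", "sdlog"),
                     positive = "sdlog"),
  loglogistic = list(dist = "llogis",   pars = c("shape", "scale"),
                     positive = c("shape", "scale")),
  gamma       = list(dist = "gamma",    pars = c("shape", "rate"),
                     positive = c("shape", "rate")),
  gengamma    = list(dist = "gengamma", pars = c("mu", "sigma", "Q"),
                     positive = "sigma")
)

family_info <- function(family) {
  info <- .family_table[[family]]
  if (is.null(info))
    stop_partsurv("unknown survival family '", family, "'; must be one of: ",
                  paste(surv_families(), collapse = ", "),
                  class = "partsurv_parameter_error")
  info
}

check_family_params <- function(family, params) {
  info <- family_info(family)
  assert_that(is.numeric(params) && !is.null(names(params)),
              "params must be a named numeric vector",
              class = "partsurv_parameter_error")
  missing <- setdiff(info$pars, names(params))
  assert_that(length(missing) == 0,
              family, " family needs parameter(s): ",
              paste(missing, collapse = ", "),
              class = "partsurv_parameter_error")
  params <- params[info$pars]
  assert_that(all(is.finite(params)), "non-finite parameter value",
              class = "partsurv_parameter_error")
  bad <- info$positive[params[info$positive] <= 0]
  assert_that(length(bad) == 0,
              family, " parameter(s) must be strictly positive: ",
              paste(bad, collapse = ", "),
              class = "partsurv_parameter_error")
  params
}

# resolve the d/p/q function for a family, searching flexsurv then stats
.dist_fun <- function(prefix, family) {
  name <- paste0(prefix, family_info(family)$dist)
  if (exists(name, envir = asNamespace("flexsurv"), inherits = FALSE))
    get(name, envir = asNamespace("flexsurv"))
  else
    get(name, envir = asNamespace("stats"))
}

family_survival_at <- function(family, params, t) {
  params <- check_family_params(family, params)
  pf <- .dist_fun("p", family)
  s <- do.call(pf, c(list(q = pmax(t, 0), lower.tail = FALSE), as.list(params)))
  ifelse(t <= 0, 1, s)
}

family_density_at <- function(family, params, t) {
  params <- check_family_params(family, params)
  df <- .dist_fun("d", family)
  do.call(df, c(list(x = t), as.list(params)))
}

family_hazard_at <- function(family, params, t) {
  params <- check_family_params(family, params)
  hname <- paste0("h", family_info(family)$dist)
  if (exists(hname, envir = asNamespace("flexsurv"), inherits = FALSE)) {
    hf <- get(hname, envir = asNamespace("flexsurv"))
    h <- do.call(hf, c(list(x = t), as.list(params)))
  } else {
    s <- family_survival_at(family, params, t)
    d <- family_density_at(family, params, t)
    h <- ifelse(s > 0, d / s, NA_real_)
  }
  pmax(h, 0)
}

# inverse survival: t such that S(t) = u
family_inv_survival <- function(family, params, u) {
  params <- check_family_params(family, params)
  qf <- .dist_fun("q", family)
  do.call(qf, c(list(p = u, lower.tail = FALSE), as.list(params)))
}

#' Survival-function objects
#'
#' A `surv_fn` wraps a vectorised survival function \eqn{S(t)} together with an
#' optional hazard, and is the common currency between the fitting module and
#' the partitioned survival engine.
#'
#' @param surv vectorised function of time returning survival probabilities.
#' @param hazard optional vectorised hazard function (per year).
#' @param label short description used in printing.
#' @return an object of class `surv_fn`.
#' @export
surv_fn <- function(surv, hazard = NULL, label = "survival function") {
  assert_that(is.function(surv), "surv must be a function",
              class = "partsurv_parameter_error")
  structure(list(surv = surv, hazard = hazard, label = label),
            class = "surv_fn")
}

#' @export
print.surv_fn <- function(x, ...) {
  cat("<surv_fn> ", x$label, "\n", sep = "")
  invisible(x)
}

#' Survival-function object for a parametric family
#'
#' @param family one of [surv_families()].
#' @param params named parameter vector on the natural scale.
#' @return a [surv_fn()].
#' @export
surv_fn_family <- function(family, params) {
  params <- check_family_params(family, params)
  surv_fn(
    surv = function(t) family_survival_at(family, params, t),
    hazard = function(t) family_hazard_at(family, params, t),
    label = paste0(family, "(", paste(names(params), "=", signif(params, 4),
                                      collapse = ", "), ")")
  )
}

#' Evaluate a survival-function object
#'
#' @param x a [surv_fn()].
#' @param t numeric vector of times (years).
#' @return survival probabilities.
#' @export
eval_surv <- function(x, t) {
  assert_that(inherits(x, "surv_fn"), "x must be a surv_fn",
              class = "partsurv_parameter_error")
  pmin(pmax(x$surv(t), 0), 1)
}
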