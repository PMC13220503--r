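`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, then restores the caller's RNG state so
#' that seeded helpers never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  code
}

stop_partsurv <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "partsurv_error")))
}

assert_that <- function(ok, ..., class = "partsurv_invalid") {
  if (!isTRUE(ok)) stop_partsurv(..., class = class)
  invisible(TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' @importFrom stats approx integrate median optim quantile runif rexp
#'   setNames weighted.mean
NULL
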