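# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state on exit.
# Every stochastic draw in the package flows through this, so identical
# (arguments, seed) pairs give byte-identical output and nothing leaks into
# the caller's random stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Multiplicative Gaussian noise: x * (1 + eps), eps ~ N(0, cv^2), truncated
# below at -0.9 so signals stay positive.
mult_noise <- function(x, cv) {
  if (cv == 0) return(x)
  eps <- pmax(rnorm(length(x), mean = 0, sd = cv), -0.9)
  x * (1 + eps)
}

#' Closed-form logistic trajectory
#'
#' \eqn{x(t) = K / (1 + ((K - x_0)/x_0) e^{-rt})}: the noiseless curve the
#' growth generator samples and the oracle the fitters are tested against.
#'
#' @param t Time(s) in hours.
#' @param r Intrinsic growth rate (1/h).
#' @param K Carrying capacity.
#' @param x0 Initial signal.
#' @return Signal value(s) at `t`.
#' @export
logistic_curve <- function(t, r, K, x0) {
  K / (1 + ((K - x0) / x0) * exp(-r * t))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bounded Levenberg-Marquardt least squares on a residual closure, via the
# raw minpack.lm::nls.lm interface (robust to exact-fit rank deficiency that
# trips nlsLM's post-hoc gradient model). Returns the parameter vector, the
# residual sum of squares and a convergence flag.
nlslm_fit <- function(resid_fn, start, lower, upper) {
  out <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  list(par = out$par, rss = out$deviance, converged = out$info %in% 1:3,
       info = out$info)
}

stop_clonefit <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_clonefit("'%s' must be a single finite number", name)
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    stop_clonefit("'%s' = %g is outside its valid range", name, x)
  invisible(x)
}
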