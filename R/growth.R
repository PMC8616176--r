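# Logistic growth fitting and clone fitness comparison.

#' Fit a logistic population growth model to one growth curve
#'
#' Least-squares fit of \eqn{x(t) = K / (1 + ((K - x_0)/x_0) e^{-rt})} on the
#' raw signal scale via Levenberg-Marquardt. The fitted intrinsic growth rate
#' `r` is the clone's absolute fitness measure; the doubling time is
#' `log(2)/r`.
#'
#' Parameters are bounded to `r` in (0, 1] /h, `K` in (max(values)/2,
#' 10 max], `x0` in (0, 3 x first positive value]; starting values are
#' `K = 1.05 max`, `x0 =` first positive value, and `r` from the slope of
#' `log(x / (K - x))` over the first half of the series. `converged` is
#' `FALSE` when the optimizer fails or any parameter sits on a bound.
#'
#' @param times Sampling times in hours (strictly increasing, >= 5 points),
#'   or a data frame with columns `time_h` and `value`.
#' @param values Signal values (confluence \% or fluorescence area), >= 0.
#' @return An object of class `logistic_fit` with components `r`, `K`, `x0`,
#'   `t_d` (doubling time), `rss`, `converged`, `fitted`, `times`, `values`.
#' @examples
#' tt <- seq(0, 264, 12)
#' fit <- fit_logistic(tt, logistic_curve(tt, log(2) / 22, 100, 1))
#' fit
#' coef(fit)
#' @seealso [time_to_threshold()], [compare_fitness()]
#' @export
fit_logistic <- function(times, values) {
  if (is.data.frame(times)) {
    if (!all(c("time_h", "value") %in% names(times)))
      stop_clonefit("data frame input needs columns 'time_h' and 'value'")
    values <- times$value
    times <- times$time_h
  }
  if (length(times) != length(values))
    stop_clonefit("'times' and 'values' must have equal length")
  if (length(times) < 5L)
    stop_clonefit("logistic fit needs at least 5 time points, got %d",
                  length(times))
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop_clonefit("times and values must be finite")
  if (any(diff(times) <= 0))
    stop_clonefit("'times' must be strictly increasing")
  if (any(values < 0))
    stop_clonefit("signal values must be non-negative")
  vmax <- max(values)
  if (vmax - min(values) < 1e-12 * max(vmax, 1))
    stop_clonefit("flat curve: all values (numerically) equal; cannot fit growth")

  first_pos <- values[values > 0][1]
  if (is.na(first_pos))
    stop_clonefit("curve has no positive signal")
  K0 <- 1.05 * vmax
  x00 <- first_pos
  # slope of the logit-transformed signal over the first half of the series
  half <- seq_len(max(5L, ceiling(length(times) / 2)))
  y <- pmin(pmax(values[half], 1e-9), K0 * (1 - 1e-9))
  z <- log(y / (K0 - y))
  r0 <- tryCatch(unname(coef(lm(z ~ times[half]))[2]), error = function(e) NA)
  if (!is.finite(r0) || r0 <= 0) r0 <- 0.03
  r0 <- min(max(r0, 1e-4), 1)

  lower <- c(r = 1e-8, K = vmax / 2, x0 = vmax * 1e-9)
  upper <- c(r = 1, K = 10 * vmax, x0 = 3 * x00)
  start <- c(r = r0, K = K0, x0 = min(x00, upper[["x0"]] * 0.9))

  fit <- tryCatch(
    nlslm_fit(function(p) values - logistic_curve(times, p[1], p[2], p[3]),
              start = unname(start), lower = unname(lower),
              upper = unname(upper)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop_clonefit("logistic fit failed: %s", conditionMessage(fit))

  est <- setNames(fit$par, c("r", "K", "x0"))
  on_bound <- any(abs(est - lower) < 1e-8 * pmax(abs(lower), 1e-8)) ||
    any(abs(est - upper) < 1e-8 * abs(upper))
  fitted_vals <- logistic_curve(times, est[["r"]], est[["K"]], est[["x0"]])
  structure(
    list(r = est[["r"]], K = est[["K"]], x0 = est[["x0"]],
         t_d = doubling_time(est[["r"]]),
         rss = sum((values - fitted_vals)^2),
         converged = fit$converged && !on_bound,
         fitted = fitted_vals, times = times, values = values),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> r = %.5f /h (t_d = %.2f h), K = %.4g, x0 = %.4g\n",
              x$r, x$t_d, x$K, x$x0))
  cat(sprintf("  n = %d points, RSS = %.4g, converged: %s\n",
              length(x$times), x$rss, x$converged))
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) {
  c(r = object$r, K = object$K, x0 = object$x0)
}

#' @export
predict.logistic_fit <- function(object, times = object$times, ...) {
  logistic_curve(times, object$r, object$K, object$x0)
}

#' @export
residuals.logistic_fit <- function(object, ...) object$values - object$fitted

#' @export
fitted.logistic_fit <- function(object, ...) object$fitted

#' @export
summary.logistic_fit <- function(object, ...) {
  out <- data.frame(r = object$r, t_d = object$t_d, K = object$K,
                    x0 = object$x0, rss = object$rss,
                    converged = object$converged)
  class(out) <- c("summary.logistic_fit", "data.frame")
  out
}

#' Time for a fitted logistic curve to reach a signal threshold
#'
#' Analytic inversion of the logistic model:
#' \eqn{t = \log\{((K - x_0)/x_0) / ((K - c)/c)\} / r} for threshold `c`.
#' Computed on the fitted model rather than the raw data for noise
#' robustness; see [time_to_threshold_raw()] for the interpolation variant.
#'
#' @param fit A [fit_logistic()] result, or any list with `r`, `K`, `x0`.
#' @param threshold Signal threshold, strictly between `x0` and `K`
#'   (e.g. 50 for time-to-50\%-confluency); `threshold = x0` returns 0.
#' @return Time in hours.
#' @export
time_to_threshold <- function(fit, threshold) {
  r <- fit$r; K <- fit$K; x0 <- fit$x0
  check_number(threshold, "threshold", 0, strict_lower = TRUE)
  if (threshold < x0 || threshold >= K)
    stop_clonefit("threshold %g outside the reachable range [x0 = %g, K = %g)",
                  threshold, x0, K)
  log(((K - x0) / x0) / ((K - threshold) / threshold)) / r
}

#' Time to threshold by linear interpolation of the raw curve
#'
#' @param times,values The raw curve.
#' @param threshold Signal threshold.
#' @return First crossing time in hours (NA if the curve never crosses).
#' @export
time_to_threshold_raw <- function(times, values, threshold) {
  above <- which(values >= threshold)
  if (!length(above)) return(NA_real_)
  i <- above[1]
  if (i == 1L) return(times[1])
  approx(values[(i - 1):i], times[(i - 1):i], xout = threshold)$y
}

#' Compare clone-group fitness with a pooled-variance t-test
#'
#' Two-sample Student t-test (pooled variance, so 5-vs-5 clones gives
#' `df = 8`) on per-clone intrinsic growth rates, plus the ratio of group
#' mean rates as the fold difference in fitness.
#'
#' @param group_a,group_b Numeric vectors of per-clone growth rates (each
#'   `n >= 2`).
#' @return An object of class `fitness_comparison`: `group_means`, `ratio`
#'   (mean A / mean B), `t_stat`, `df`, `p_value`, `infinite_t` flag (set
#'   when pooled variance is zero with unequal means).
#' @export
compare_fitness <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop_clonefit("each group needs at least 2 clones")
  m <- c(a = mean(group_a), b = mean(group_b))
  df <- length(group_a) + length(group_b) - 2L
  pooled_var <- (sum((group_a - m["a"])^2) + sum((group_b - m["b"])^2)) / df
  infinite_t <- FALSE
  if (pooled_var == 0) {
    if (m["a"] == m["b"]) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- list(statistic = sign(m["a"] - m["b"]) * Inf, p.value = 0)
      infinite_t <- TRUE
    }
  } else {
    ht <- t.test(group_a, group_b, var.equal = TRUE)
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  structure(
    list(group_means = unname(m), ratio = unname(m["a"] / m["b"]),
         t_stat = unname(tt$statistic), df = df, p_value = tt$p.value,
         n = c(length(group_a), length(group_b)), infinite_t = infinite_t),
    class = "fitness_comparison"
  )
}

#' @export
print.fitness_comparison <- function(x, ...) {
  cat(sprintf("<fitness_comparison> mean A = %.5g, mean B = %.5g (ratio %.3f)\n",
              x$group_means[1], x$group_means[2], x$ratio))
  cat(sprintf("  pooled t = %.3f, df = %d, p = %.4g%s\n", x$t_stat, x$df,
              x$p_value, if (x$infinite_t) " [zero pooled variance]" else ""))
  invisible(x)
}

#' Ordinary least-squares correlation
#'
#' Simple linear regression reporting slope, intercept and R-squared, e.g.
#' for relating expression level to proliferative time or drug sensitivity
#' to growth rate.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`; `x` must vary.
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop_clonefit("'x' and 'y' lengths differ")
  if (length(x) < 3L) stop_clonefit("correlation needs n >= 3")
  if (var(x) == 0) stop_clonefit("'x' has zero variance")
  fit <- lm(y ~ x)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 0 else 1 - sum(residuals(fit)^2) / tss
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = min(max(r2, 0), 1), n = length(x)),
    class = "ols_correlation"
  )
}

#' @export
print.ols_correlation <- function(x, ...) {
  cat(sprintf("<ols_correlation> y = %.4g x + %.4g, R^2 = %.4f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Fit every replicate curve in a table and summarize per clone
#'
#' Fits [fit_logistic()] to each (clone, replicate, channel) series and
#' averages the fitted parameters per clone (replicates are fitted
#' independently, then summarized by the mean).
#'
#' @param curves Data frame in the curve dialect (`clone`, `replicate`,
#'   `channel`, `time_h`, `value`).
#' @param threshold Optional signal threshold for a time-to-threshold column
#'   (skipped per replicate when outside that fit's (x0, K)).
#' @return List with `fits` (per-replicate `logistic_fit`s, named
#'   `clone.replicate.channel`) and `summary` (per-clone data frame with mean
#'   `r`, `K`, `x0`, `t_d`, `t_thresh`, `rss`, `n_replicates`, `converged` =
#'   all replicates converged).
#' @export
growth_summary <- function(curves, threshold = NULL) {
  need <- c("clone", "replicate", "channel", "time_h", "value")
  if (!all(need %in% names(curves)))
    stop_clonefit("curves must have columns %s", paste(need, collapse = ", "))
  key <- interaction(curves$clone, curves$replicate, curves$channel,
                     drop = TRUE)
  fits <- lapply(split(curves, key), function(d) {
    d <- d[order(d$time_h), ]
    fit_logistic(d$time_h, d$value)
  })
  clone_of <- vapply(split(curves$clone, key), `[`, "", 1)
  per_clone <- lapply(split(seq_along(fits), clone_of), function(idx) {
    fs <- fits[idx]
    tth <- NA_real_
    if (!is.null(threshold)) {
      vals <- vapply(fs, function(f) {
        if (threshold > f$x0 && threshold < f$K)
          time_to_threshold(f, threshold) else NA_real_
      }, 1)
      tth <- mean(vals, na.rm = TRUE)
    }
    data.frame(
      r = mean(vapply(fs, `[[`, 1, "r")),
      K = mean(vapply(fs, `[[`, 1, "K")),
      x0 = mean(vapply(fs, `[[`, 1, "x0")),
      t_d = doubling_time(mean(vapply(fs, `[[`, 1, "r"))),
      t_thresh = tth,
      rss = mean(vapply(fs, `[[`, 1, "rss")),
      n_replicates = length(fs),
      converged = all(vapply(fs, `[[`, TRUE, "converged")))
  })
  summary <- do.call(rbind, per_clone)
  summary <- cbind(clone = names(per_clone), summary)
  rownames(summary) <- NULL
  list(fits = fits, summary = summary)
}
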