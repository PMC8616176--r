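# Two-clone Lotka-Volterra competition: simulation, two-stage fitting and
# residual bootstrap. The model (s = sensitive, r = resistant):
#
#   dx_s/dt = r_s x_s (1 - (x_s + alpha_sr x_r) / K_s)
#   dx_r/dt = r_r x_r (1 - (x_r + alpha_rs x_s) / K_r)
#
# alpha_sr is the per-capita crowding effect of the resistant clone on the
# sensitive clone, normalized by the focal clone's carrying capacity; the
# ratio alpha_rs / alpha_sr measures competitive asymmetry (how much harder
# the sensitive clone hits the resistant one than vice versa).

#' Construct Lotka-Volterra competition parameters
#'
#' @param r_s,r_r Intrinsic growth rates (1/h) of the sensitive and resistant
#'   clone.
#' @param K_s,K_r Carrying capacities in each clone's own signal units.
#' @param alpha_sr Competitive effect of resistant on sensitive (>= 0).
#' @param alpha_rs Competitive effect of sensitive on resistant (>= 0).
#' @return An object of class `lv_params`.
#' @export
lv_params <- function(r_s, r_r, K_s, K_r, alpha_sr, alpha_rs) {
  for (nm in c("r_s", "r_r", "K_s", "K_r"))
    check_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  check_number(alpha_sr, "alpha_sr", lower = 0)
  check_number(alpha_rs, "alpha_rs", lower = 0)
  structure(list(r_s = r_s, r_r = r_r, K_s = K_s, K_r = K_r,
                 alpha_sr = alpha_sr, alpha_rs = alpha_rs),
            class = "lv_params")
}

#' Simulate the two-clone competitive Lotka-Volterra system
#'
#' Numerical solution with `deSolve::ode` (adaptive `lsoda`, rtol 1e-8,
#' atol 1e-10 by default; fixed-step `rk4` available for reproducibility
#' checks). With `alpha_sr = alpha_rs = 0` each trajectory is the closed-form
#' logistic; a clone seeded at 0 stays at 0.
#'
#' @param params An [lv_params()] object (or compatible list).
#' @param initial Length-2 vector `c(x_s0, x_r0)` of initial signals (>= 0).
#' @param times Output times in hours (increasing).
#' @param method `deSolve` integrator name.
#' @param rtol,atol Integration tolerances.
#' @return Data frame with columns `time_h`, `x_s`, `x_r`.
#' @export
simulate_lv <- function(params, initial, times, method = "lsoda",
                        rtol = 1e-8, atol = 1e-10) {
  if (length(initial) != 2L || any(initial < 0))
    stop_clonefit("'initial' must be two non-negative values c(x_s0, x_r0)")
  if (any(diff(times) <= 0)) stop_clonefit("'times' must be increasing")
  p <- params
  rhs <- function(t, y, parms) {
    xs <- y[1]; xr <- y[2]
    list(c(p$r_s * xs * (1 - (xs + p$alpha_sr * xr) / p$K_s),
           p$r_r * xr * (1 - (xr + p$alpha_rs * xs) / p$K_r)))
  }
  t0 <- times[1]
  sol <- tryCatch(
    deSolve::ode(y = c(xs = initial[1], xr = initial[2]),
                 times = if (t0 > 0) c(0, times) else times,
                 func = rhs, parms = NULL, method = method,
                 rtol = rtol, atol = atol),
    error = function(e) e)
  if (inherits(sol, "error") || any(!is.finite(sol)))
    stop_clonefit(
      "LV integration failed (r_s=%g, r_r=%g, K_s=%g, K_r=%g, alpha_sr=%g, alpha_rs=%g): %s",
      p$r_s, p$r_r, p$K_s, p$K_r, p$alpha_sr, p$alpha_rs,
      if (inherits(sol, "error")) conditionMessage(sol) else "non-finite state")
  sol <- as.data.frame(sol)
  sol <- sol[match(times, sol$time), ]
  data.frame(time_h = times, x_s = sol$xs, x_r = sol$xr)
}

#' Fit the Lotka-Volterra competition model to mono- and co-culture curves
#'
#' Joint maximum-likelihood-style fit. Each clone's monoculture replicates
#' are first fitted with [fit_logistic()] to obtain starting values (and are
#' reported as `mono_fits`); all dynamics parameters — `r_s`, `r_r`, `K_s`,
#' `K_r`, `alpha_sr`, `alpha_rs`, the monoculture seeding signals and the
#' co-culture seeding density — are then estimated together by
#' Levenberg-Marquardt least squares on log-scale residuals over every
#' monoculture and co-culture observation. Log residuals are the natural
#' weighting for multiplicative (constant-CV) measurement noise; fitting the
#' monocultures jointly with the co-cultures matters because a slow clone may
#' not approach its carrying capacity within the observation horizon, leaving
#' a monoculture-only `K` estimate badly determined. Each channel's `K`
#' absorbs that channel's fluorescence scale.
#'
#' When the table carries the seeded sensitive fraction (`frac_s`, as written
#' by [gen_coculture()]) each co-culture's initial state is constrained to
#' `(frac_s, 1 - frac_s) * N0` with a single shared seeding density `N0`
#' estimated from the data — seeding ratios are experimenter-controlled
#' metadata. Without `frac_s` the two initial signals of every co-culture
#' condition are free parameters.
#'
#' @param curves Data frame in the co-culture dialect produced by
#'   [gen_coculture()] / [read_timeseries_csv()]: columns `clone`,
#'   `replicate`, `channel`, `time_h`, `value`, `culture`
#'   (`mono_s`/`mono_r`/`coculture`), optionally `frac_s`. Channel `yellow`
#'   reads the sensitive clone, `red` the resistant clone (override via
#'   `channel_map`).
#' @param channel_map Named character vector mapping roles to channels.
#' @param use_seeding_fractions Constrain co-culture initial states to the
#'   known seeding fractions when `frac_s` is available (default `TRUE`).
#' @return An object of class `lv_fit`: `params` ([lv_params()]), `ratio`
#'   (`alpha_rs / alpha_sr`), `rss` (sum of squared log residuals),
#'   `converged`, `mono_fits`, and the data needed for [bootstrap_lv()].
#' @export
fit_lv <- function(curves,
                   channel_map = c(sensitive = "yellow", resistant = "red"),
                   use_seeding_fractions = TRUE) {
  need <- c("clone", "replicate", "channel", "time_h", "value", "culture")
  if (!all(need %in% names(curves)))
    stop_clonefit("curves must have columns %s", paste(need, collapse = ", "))
  mono_s <- curves[curves$culture == "mono_s" &
                     curves$channel == channel_map[["sensitive"]], ]
  mono_r <- curves[curves$culture == "mono_r" &
                     curves$channel == channel_map[["resistant"]], ]
  coc <- curves[curves$culture == "coculture", ]
  if (!nrow(mono_s) || !nrow(mono_r) || !nrow(coc))
    stop_clonefit("need monocultures for both clones and at least one co-culture")
  if (any(curves$value <= 0))
    stop_clonefit("signal values must be positive for the log-scale fit")

  fit_monos <- function(d) {
    lapply(split(d, interaction(d$clone, d$replicate, drop = TRUE)),
           function(x) fit_logistic(x$time_h[order(x$time_h)],
                                    x$value[order(x$time_h)]))
  }
  fits_s <- fit_monos(mono_s)
  fits_r <- fit_monos(mono_r)
  mean_par <- function(fits, nm) mean(vapply(fits, `[[`, 1, nm))

  conditions <- lapply(split(coc, coc$clone, drop = TRUE), function(d) {
    times <- sort(unique(d$time_h))
    t0 <- times[1]
    init_s <- mean(d$value[d$time_h == t0 & d$channel == channel_map[["sensitive"]]])
    init_r <- mean(d$value[d$time_h == t0 & d$channel == channel_map[["resistant"]]])
    frac_s <- if ("frac_s" %in% names(d)) d$frac_s[1] else NA_real_
    obs_s <- d[d$channel == channel_map[["sensitive"]], c("time_h", "value")]
    obs_r <- d[d$channel == channel_map[["resistant"]], c("time_h", "value")]
    list(times = times, init = c(init_s, init_r), frac_s = frac_s,
         obs_s = obs_s, obs_r = obs_r)
  })
  nc <- length(conditions)
  constrain <- use_seeding_fractions &&
    !any(is.na(vapply(conditions, `[[`, 1, "frac_s")))

  vmax <- max(curves$value)
  # parameter vector: r_s r_r K_s K_r alpha_sr alpha_rs x0_mono_s x0_mono_r,
  # then N0 (constrained) or per-condition (x_s0, x_r0) (free)
  start <- c(mean_par(fits_s, "r"), mean_par(fits_r, "r"),
             mean_par(fits_s, "K"),
             min(mean_par(fits_r, "K"), 2 * max(mono_r$value)),
             0.5, 0.5, mean_par(fits_s, "x0"), mean_par(fits_r, "x0"))
  init_pars <- if (constrain) {
    mean(vapply(conditions, function(cond) sum(cond$init), 1))
  } else {
    pmax(unlist(lapply(conditions, `[[`, "init")), vmax * 1e-6)
  }
  start <- c(start, init_pars)
  np <- length(start)
  lower <- c(1e-5, 1e-5, vmax * 1e-3, vmax * 1e-3, 0, 0,
             rep(vmax * 1e-9, np - 6))
  upper <- c(1, 1, 100 * vmax, 100 * vmax, 5, 5, rep(vmax, np - 6))

  resid_fn <- function(p) {
    lv <- list(r_s = p[1], r_r = p[2], K_s = p[3], K_r = p[4],
               alpha_sr = p[5], alpha_rs = p[6])
    out <- c(
      log(mono_s$value) -
        log(pmax(logistic_curve(mono_s$time_h, p[1], p[3], p[7]), 1e-12)),
      log(mono_r$value) -
        log(pmax(logistic_curve(mono_r$time_h, p[2], p[4], p[8]), 1e-12)))
    for (i in seq_len(nc)) {
      cond <- conditions[[i]]
      init <- if (constrain) {
        c(cond$frac_s, 1 - cond$frac_s) * p[8 + 1]
      } else {
        p[8 + 2 * (i - 1) + 1:2]
      }
      traj <- tryCatch(simulate_lv(lv, init, cond$times),
                       error = function(e) NULL)
      if (is.null(traj))
        return(rep(1e6, length(out) + nrow(cond$obs_s) + nrow(cond$obs_r)))
      pred_s <- pmax(traj$x_s[match(cond$obs_s$time_h, traj$time_h)], 1e-12)
      pred_r <- pmax(traj$x_r[match(cond$obs_r$time_h, traj$time_h)], 1e-12)
      out <- c(out, log(cond$obs_s$value) - log(pred_s),
               log(cond$obs_r$value) - log(pred_r))
    }
    out
  }

  fit <- nlslm_fit(resid_fn, start = unname(start), lower = lower,
                   upper = upper)
  p <- fit$par
  alpha_sr <- p[5]; alpha_rs <- p[6]

  # Unidentifiable when the co-cultures carry no information about crowding:
  # the objective is then flat in the alphas.
  p0 <- p; p0[5:6] <- 0
  flat <- (alpha_sr > 1e-6 || alpha_rs > 1e-6) &&
    abs(sum(resid_fn(p0)^2) - fit$rss) <= 1e-10 * max(fit$rss, 1)

  fitted_inits <- lapply(seq_len(nc), function(i) {
    if (constrain) {
      c(conditions[[i]]$frac_s, 1 - conditions[[i]]$frac_s) * p[9]
    } else {
      p[8 + 2 * (i - 1) + 1:2]
    }
  })
  names(fitted_inits) <- names(conditions)

  structure(
    list(params = lv_params(p[1], p[2], p[3], p[4], alpha_sr, alpha_rs),
         ratio = if (alpha_sr > 0) alpha_rs / alpha_sr else Inf,
         rss = fit$rss, converged = fit$converged && !flat,
         seeding_density = if (constrain) p[9] else NA_real_,
         x0_mono = c(sensitive = p[7], resistant = p[8]),
         fitted_inits = fitted_inits,
         mono_fits = list(sensitive = fits_s, resistant = fits_r),
         conditions = conditions, channel_map = channel_map,
         constrained_init = constrain, curves = curves),
    class = "lv_fit"
  )
}

# Model prediction for every row of fit$curves under the joint fit.
lv_fitted_values <- function(fit) {
  curves <- fit$curves
  p <- fit$params
  pred <- numeric(nrow(curves))
  sel_ms <- curves$culture == "mono_s" &
    curves$channel == fit$channel_map[["sensitive"]]
  sel_mr <- curves$culture == "mono_r" &
    curves$channel == fit$channel_map[["resistant"]]
  pred[sel_ms] <- logistic_curve(curves$time_h[sel_ms], p$r_s, p$K_s,
                                 fit$x0_mono[["sensitive"]])
  pred[sel_mr] <- logistic_curve(curves$time_h[sel_mr], p$r_r, p$K_r,
                                 fit$x0_mono[["resistant"]])
  for (cond_name in names(fit$conditions)) {
    cond <- fit$conditions[[cond_name]]
    traj <- simulate_lv(p, fit$fitted_inits[[cond_name]], cond$times)
    sel_s <- curves$clone == cond_name &
      curves$channel == fit$channel_map[["sensitive"]]
    sel_r <- curves$clone == cond_name &
      curves$channel == fit$channel_map[["resistant"]]
    pred[sel_s] <- traj$x_s[match(curves$time_h[sel_s], traj$time_h)]
    pred[sel_r] <- traj$x_r[match(curves$time_h[sel_r], traj$time_h)]
  }
  pred
}

#' Fitted values and residuals of a Lotka-Volterra fit
#' @param object An `lv_fit`.
#' @param ... Unused.
#' @export
fitted.lv_fit <- function(object, ...) lv_fitted_values(object)

#' @rdname fitted.lv_fit
#' @export
residuals.lv_fit <- function(object, ...) {
  object$curves$value - lv_fitted_values(object)
}

#' @export
print.lv_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("<lv_fit> r_s = %.5f, r_r = %.5f, K_s = %.4g, K_r = %.4g\n",
              p$r_s, p$r_r, p$K_s, p$K_r))
  cat(sprintf("  alpha_sr = %.4f, alpha_rs = %.4f  (ratio alpha_rs/alpha_sr = %.3f)\n",
              p$alpha_sr, p$alpha_rs, x$ratio))
  cat(sprintf("  co-culture RSS = %.4g, converged: %s\n", x$rss, x$converged))
  invisible(x)
}

#' @export
coef.lv_fit <- function(object, ...) {
  p <- object$params
  c(r_s = p$r_s, r_r = p$r_r, K_s = p$K_s, K_r = p$K_r,
    alpha_sr = p$alpha_sr, alpha_rs = p$alpha_rs)
}

#' @export
summary.lv_fit <- function(object, ...) {
  out <- as.data.frame(as.list(coef(object)))
  out$ratio <- object$ratio
  out$rss <- object$rss
  out$converged <- object$converged
  out
}

#' Residual-resampling bootstrap for a Lotka-Volterra fit
#'
#' Resamples residuals with replacement within each curve (every
#' condition x replicate x channel series, monocultures included), rebuilds
#' pseudo-data around the fitted trajectories and refits. Residuals are
#' taken and resampled on the multiplicative scale (observed/fitted
#' factors), matching the constant-CV noise model — additive resampling
#' would move plateau-sized residuals onto near-zero early time points.
#' Each resample uses the derived seed `seed + i`, so extending `n_boot`
#' with the same seed leaves earlier resamples unchanged.
#'
#' @param fit An [fit_lv()] result.
#' @param n_boot Number of resamples (>= 100 recommended; default 1000).
#' @param seed Integer seed.
#' @return An object of class `lv_boot`: `estimates` (data frame with
#'   `alpha_sr`, `alpha_rs`, `ratio`, `converged` per resample), `point`
#'   (the original fit's values), `prop_nonconverged`, and a `warning` string
#'   when more than 20\% of resamples fail to converge.
#' @export
bootstrap_lv <- function(fit, n_boot = 1000, seed = 1) {
  stopifnot(inherits(fit, "lv_fit"))
  n_boot <- as.integer(check_number(n_boot, "n_boot", 1))
  curves <- fit$curves
  key <- interaction(curves$clone, curves$replicate, curves$channel,
                     drop = TRUE)
  pred <- lv_fitted_values(fit)
  factor_resid <- curves$value / pred

  one_resample <- function(i) {
    new_vals <- with_seed(seed + i, {
      v <- numeric(nrow(curves))
      for (lv in levels(key)) {
        idx <- which(key == lv)
        v[idx] <- pred[idx] *
          sample(factor_resid[idx], length(idx), replace = TRUE)
      }
      v
    })
    boot_curves <- curves
    boot_curves$value <- new_vals
    bf <- tryCatch(fit_lv(boot_curves, channel_map = fit$channel_map,
                          use_seeding_fractions = fit$constrained_init),
                   error = function(e) NULL)
    if (is.null(bf))
      return(data.frame(alpha_sr = NA_real_, alpha_rs = NA_real_,
                        ratio = NA_real_, converged = FALSE))
    data.frame(alpha_sr = bf$params$alpha_sr, alpha_rs = bf$params$alpha_rs,
               ratio = bf$ratio, converged = bf$converged)
  }
  estimates <- do.call(rbind, lapply(seq_len(n_boot), one_resample))
  rownames(estimates) <- NULL
  prop_bad <- mean(!estimates$converged)
  warn <- if (prop_bad > 0.2)
    sprintf("%.0f%% of bootstrap resamples failed to converge",
            100 * prop_bad) else NULL
  if (!is.null(warn)) warning(warn, call. = FALSE)
  structure(
    list(estimates = estimates,
         point = c(alpha_sr = fit$params$alpha_sr,
                   alpha_rs = fit$params$alpha_rs, ratio = fit$ratio),
         prop_nonconverged = prop_bad, warning = warn,
         n_boot = n_boot, seed = seed),
    class = "lv_boot"
  )
}

#' @export
print.lv_boot <- function(x, ...) {
  q <- quantile(x$estimates$ratio, c(0.025, 0.25, 0.5, 0.75, 0.975),
                na.rm = TRUE)
  cat(sprintf("<lv_boot> %d resamples (%.0f%% non-converged)\n",
              x$n_boot, 100 * x$prop_nonconverged))
  cat(sprintf("  ratio point estimate %.3f; quantiles 2.5/25/50/75/97.5%%: %s\n",
              x$point[["ratio"]], paste(sprintf("%.3f", q), collapse = " ")))
  invisible(x)
}

#' @export
quantile.lv_boot <- function(x, probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
                             ...) {
  sapply(x$estimates[c("alpha_sr", "alpha_rs", "ratio")],
         quantile, probs = probs, na.rm = TRUE)
}
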