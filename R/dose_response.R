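# Dose-response analysis: four-parameter logistic viability fits (absolute
# IC50), normalized growth-rate inhibition (GR) metrics and GR50, mixture
# predictions under independent action, and group comparisons.

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of control-normalized viability
#' \eqn{v(d) = bottom + (top - bottom) / (1 + (d/ec50)^{hill})} with `hill`
#' constrained positive (viability decreasing in dose). The absolute IC50 —
#' the dose at which viability is 50\% of the vehicle control — is solved
#' from the fitted curve and reported alongside the curve midpoint
#' `ec50_rel`; the two coincide only when `top = 1` and `bottom = 0`.
#'
#' Monotone-increasing viability cannot satisfy the decreasing-form
#' constraint; such fits return with `converged = FALSE` rather than an
#' error.
#'
#' @param dose Doses (> 0), at least 4 distinct values.
#' @param response Viability fractions (treated / control), same length.
#' @return An object of class `fourpl_fit`: `top`, `bottom`, `hill`,
#'   `ec50_rel`, `ic50_abs` (NA with `ic50_defined = FALSE` when the fitted
#'   curve never crosses 0.5), `rss`, `converged`.
#' @examples
#' d <- 10^seq(-1, 3, length.out = 9)
#' fit <- fit_4pl(d, 1 / (1 + d / 10))
#' fit$ic50_abs
#' @export
fit_4pl <- function(dose, response) {
  if (length(dose) != length(response))
    stop_clonefit("'dose' and 'response' lengths differ")
  keep <- is.finite(dose) & is.finite(response)
  dose <- dose[keep]; response <- response[keep]
  if (length(unique(dose)) < 4L)
    stop_clonefit("4PL fit needs at least 4 distinct doses")
  if (any(dose <= 0)) stop_clonefit("doses must be strictly positive")

  start <- c(top = max(response), bottom = min(response), hill = 1,
             ec50 = exp(mean(log(range(dose)))))
  lower <- c(top = min(response), bottom = min(min(response), 0) - 1e-9,
             hill = 1e-3, ec50 = min(dose) / 1e4)
  upper <- c(top = max(response) * 2 + 1e-9, bottom = max(response),
             hill = 20, ec50 = max(dose) * 1e4)
  fourpl <- function(d, p) p[2] + (p[1] - p[2]) / (1 + (d / p[4])^p[3])
  fit <- tryCatch(
    nlslm_fit(function(p) response - fourpl(dose, p),
              start = unname(start), lower = unname(lower),
              upper = unname(upper)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop_clonefit("4PL fit failed: %s", conditionMessage(fit))
  est <- as.list(setNames(fit$par, c("top", "bottom", "hill", "ec50")))
  pred <- fourpl(dose, fit$par)
  rss <- sum((response - pred)^2)

  # In this parameterization `top` is the low-dose and `bottom` the
  # high-dose asymptote; fitted bottom > top means viability increases with
  # dose, which violates the model: report non-converged.
  increasing <- est$bottom > est$top + 1e-9
  converged <- fit$converged && !increasing

  ic50 <- NA_real_
  ic50_defined <- FALSE
  if (est$bottom < 0.5 && est$top > 0.5) {
    ic50 <- est$ec50 * ((est$top - est$bottom) / (0.5 - est$bottom) - 1)^(1 / est$hill)
    ic50_defined <- is.finite(ic50) && ic50 > 0
  }
  structure(
    c(est[c("top", "bottom", "hill")],
      list(ec50_rel = est$ec50, ic50_abs = ic50, ic50_defined = ic50_defined,
           rss = rss, converged = converged, dose = dose,
           response = response)),
    class = "fourpl_fit"
  )
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf("<fourpl_fit> top = %.3f, bottom = %.3f, hill = %.3f, ec50_rel = %.4g\n",
              x$top, x$bottom, x$hill, x$ec50_rel))
  cat(sprintf("  absolute IC50 = %s, RSS = %.4g, converged: %s\n",
              if (x$ic50_defined) sprintf("%.4g", x$ic50_abs) else "undefined",
              x$rss, x$converged))
  invisible(x)
}

#' @export
coef.fourpl_fit <- function(object, ...) {
  c(top = object$top, bottom = object$bottom, hill = object$hill,
    ec50_rel = object$ec50_rel)
}

#' @export
predict.fourpl_fit <- function(object, dose = object$dose, ...) {
  object$bottom + (object$top - object$bottom) /
    (1 + (dose / object$ec50_rel)^object$hill)
}

#' Fold resistance between two clone groups
#'
#' Ratio of arithmetic group-mean IC50s, resistant over sensitive. Undefined
#' IC50s (NA) are excluded with a warning.
#'
#' @param group_pos IC50s of the resistant (fusion-positive) clones.
#' @param group_neg IC50s of the sensitive (fusion-negative) clones.
#' @return The fold resistance `mean(group_pos) / mean(group_neg)` at full
#'   precision (conventionally reported to one decimal).
#' @examples
#' fold_resistance(55.26, 14.48)  # ~3.8
#' @export
fold_resistance <- function(group_pos, group_neg) {
  drop_na <- function(x, nm) {
    bad <- !is.finite(x)
    if (any(bad))
      warning(sprintf("excluding %d undefined IC50(s) from %s", sum(bad), nm),
              call. = FALSE)
    x[!bad]
  }
  group_pos <- drop_na(group_pos, "group_pos")
  group_neg <- drop_na(group_neg, "group_neg")
  if (!length(group_pos) || !length(group_neg))
    stop_clonefit("both groups need at least one defined IC50")
  if (any(c(group_pos, group_neg) <= 0))
    stop_clonefit("IC50s must be positive")
  mean(group_pos) / mean(group_neg)
}

#' Normalized growth-rate inhibition (GR) value
#'
#' \deqn{GR = 2^{\log_2(x_c/x_0) / \log_2(x_{ctrl}/x_0)} - 1}
#' where `x_c` is the treated end-point count, `x0` the count at time of
#' treatment, and `x_ctrl` the vehicle-control end-point count. GR = 1 means
#' no drug effect, GR = 0 complete cytostasis, GR < 0 net cell loss. Because
#' the drug effect is measured per division, GR is insensitive to differences
#' in division rate that confound end-point IC50s.
#'
#' @param x_c Treated count(s) (> 0; vectorized).
#' @param x0 Count at time of treatment (> 0).
#' @param x_ctrl Vehicle-control end-point count (must exceed `x0`: no
#'   control growth means GR is undefined).
#' @return GR value(s) in (-1, 1] for `0 < x_c <= x_ctrl`.
#' @examples
#' compute_gr(200, 100, 800)  # 2^(1/3) - 1
#' @export
compute_gr <- function(x_c, x0, x_ctrl) {
  check_number(x0, "x0", 0, strict_lower = TRUE)
  check_number(x_ctrl, "x_ctrl", 0, strict_lower = TRUE)
  if (x_ctrl <= x0)
    stop_clonefit("GR undefined: control count (%g) must exceed the initial count (%g)",
                  x_ctrl, x0)
  if (any(x_c <= 0)) stop_clonefit("treated counts must be positive")
  2^(log2(x_c / x0) / log2(x_ctrl / x0)) - 1
}

#' Fit a GR dose-response curve and derive GR50
#'
#' Fits \eqn{GR(c) = GR_{inf} + (1 - GR_{inf}) / (1 + (c/GEC_{50})^{h})} by
#' least squares and solves GR = 0.5 for GR50. The GR50 is flagged UTBD
#' ("unable to be determined") when the fitted curve is flat
#' (`|1 - GR_inf| < 0.1` over the tested range) or never reaches 0.5 within
#' the tested dose range; an all-GR-near-1 input yields UTBD, not an error.
#'
#' @param dose Doses (> 0), >= 4 with defined GR.
#' @param gr GR values per dose (see [compute_gr()]).
#' @param flat_tol Flatness threshold on `1 - GR_inf` for the UTBD call.
#' @return An object of class `gr_fit`: `gr50` (NA when UTBD), `utbd`,
#'   `utbd_reason`, `gr_inf`, `gec50`, `h_gr`, `rss`, plus the data.
#' @export
fit_gr_curve <- function(dose, gr, flat_tol = 0.1) {
  if (length(dose) != length(gr))
    stop_clonefit("'dose' and 'gr' lengths differ")
  keep <- is.finite(dose) & is.finite(gr)
  dose <- dose[keep]; gr <- gr[keep]
  if (length(unique(dose)) < 4L)
    stop_clonefit("GR curve fit needs at least 4 distinct doses with defined GR")
  if (any(dose <= 0)) stop_clonefit("doses must be strictly positive")

  start <- c(gr_inf = min(gr), gec50 = exp(mean(log(range(dose)))), h = 1)
  lower <- c(gr_inf = -1, gec50 = min(dose) / 1e4, h = 1e-3)
  upper <- c(gr_inf = 1 + 1e-9, gec50 = max(dose) * 1e4, h = 20)
  grc <- function(d, p) p[1] + (1 - p[1]) / (1 + (d / p[2])^p[3])
  fit <- tryCatch(
    nlslm_fit(function(p) gr - grc(dose, p),
              start = unname(start), lower = unname(lower),
              upper = unname(upper)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop_clonefit("GR curve fit failed: %s", conditionMessage(fit))
  est <- as.list(setNames(fit$par, c("gr_inf", "gec50", "h_gr")))
  pred <- grc(dose, fit$par)
  rss <- sum((gr - pred)^2)

  utbd <- FALSE; utbd_reason <- NA_character_; gr50 <- NA_real_
  if (abs(1 - est$gr_inf) < flat_tol) {
    utbd <- TRUE; utbd_reason <- "flat GR dose curve"
  } else if (est$gr_inf >= 0.5) {
    utbd <- TRUE; utbd_reason <- "fitted curve never reaches GR = 0.5"
  } else {
    gr50 <- est$gec50 * (0.5 / (0.5 - est$gr_inf))^(1 / est$h_gr)
    if (!is.finite(gr50) || gr50 < min(dose) || gr50 > max(dose)) {
      # crossing outside the tested dose range
      utbd <- TRUE
      utbd_reason <- "GR = 0.5 crossing outside tested dose range"
      gr50 <- NA_real_
    }
  }
  structure(
    c(est, list(gr50 = gr50, utbd = utbd, utbd_reason = utbd_reason,
                rss = rss, dose = dose, gr = gr)),
    class = "gr_fit"
  )
}

#' @export
print.gr_fit <- function(x, ...) {
  cat(sprintf("<gr_fit> GR_inf = %.3f, GEC50 = %.4g, h = %.3f\n",
              x$gr_inf, x$gec50, x$h_gr))
  if (x$utbd) {
    cat(sprintf("  GR50: UTBD (%s)\n", x$utbd_reason))
  } else {
    cat(sprintf("  GR50 = %.4g (RSS = %.4g)\n", x$gr50, x$rss))
  }
  invisible(x)
}

#' @export
coef.gr_fit <- function(object, ...) {
  c(gr_inf = object$gr_inf, gec50 = object$gec50, h_gr = object$h_gr)
}

#' @export
predict.gr_fit <- function(object, dose = object$dose, ...) {
  object$gr_inf + (1 - object$gr_inf) /
    (1 + (dose / object$gec50)^object$h_gr)
}

#' Predict the dose-response of a clonal mixture under independent action
#'
#' Mixture survival is the fraction-weighted average of the pure-clone
#' curves, \eqn{S(d) = (1-f) S_{neg}(d) + f S_{pos}(d)}, with the mixture
#' IC50 located by root bisection of `S(d) = 0.5` over
#' `[min dose / 100, max dose * 100]`. Under this model the predicted IC50
#' is monotone in `f` — any empirical finding that mixtures track the pure
#' sensitive clone therefore indicates stronger-than-independent killing.
#'
#' @param fit_neg,fit_pos Converged [fit_4pl()] results for the sensitive and
#'   resistant clone.
#' @param f Fraction of resistant (fusion-positive) cells, in `[0, 1]`.
#' @return An object of class `mixture_prediction`: `f`, `ic50`
#'   (NA with `defined = FALSE` when `S` never crosses 0.5 in the bracket),
#'   and `survival(d)`, the predicted mixture survival function.
#' @export
predict_mixture_ic50 <- function(fit_neg, fit_pos, f) {
  stopifnot(inherits(fit_neg, "fourpl_fit"), inherits(fit_pos, "fourpl_fit"))
  if (!fit_neg$converged || !fit_pos$converged)
    stop_clonefit("both 4PL fits must have converged")
  check_number(f, "f", 0, 1)
  survival <- function(d) {
    (1 - f) * predict(fit_neg, d) + f * predict(fit_pos, d)
  }
  lo <- min(fit_neg$dose, fit_pos$dose) / 100
  hi <- max(fit_neg$dose, fit_pos$dose) * 100
  ic50 <- NA_real_; defined <- FALSE
  g <- function(d) survival(d) - 0.5
  if (g(lo) * g(hi) < 0) {
    ic50 <- uniroot(g, c(lo, hi), tol = 1e-10)$root
    defined <- TRUE
  }
  structure(list(f = f, ic50 = ic50, defined = defined, survival = survival,
                 bracket = c(lo, hi)),
            class = "mixture_prediction")
}

#' @export
print.mixture_prediction <- function(x, ...) {
  cat(sprintf("<mixture_prediction> f(positive) = %.2f, predicted IC50 = %s\n",
              x$f, if (x$defined) sprintf("%.4g", x$ic50) else "undefined"))
  invisible(x)
}

#' Compare replicate IC50s of mixtures against the pure-clone conditions
#'
#' Two-sided Student t-tests of every condition against the 100\%-sensitive
#' and 100\%-resistant references, labelling non-significant comparisons
#' (p >= 0.05) "NS".
#'
#' @param ic50s Named list of numeric vectors of replicate IC50s; must
#'   include the two reference conditions.
#' @param neg,pos Names of the pure sensitive / pure resistant conditions.
#' @param alpha Significance threshold for the NS label.
#' @return Data frame with `condition`, `n`, `mean_ic50`, `p_vs_negative`,
#'   `p_vs_positive` and the corresponding `label_*` columns.
#' @export
compare_group_ic50 <- function(ic50s, neg = "neg_100", pos = "pos_100",
                               alpha = 0.05) {
  if (!all(c(neg, pos) %in% names(ic50s)))
    stop_clonefit("'ic50s' must contain the reference conditions '%s' and '%s'",
                  neg, pos)
  if (any(vapply(ic50s, length, 1L) < 3L))
    stop_clonefit("every condition needs at least 3 replicate IC50s")
  p_vs <- function(x, ref) {
    if (identical(x, ref) || (var(x) == 0 && var(ref) == 0)) {
      if (mean(x) == mean(ref)) return(1)
      return(0)
    }
    t.test(x, ref, var.equal = TRUE)$p.value
  }
  rows <- lapply(names(ic50s), function(nm) {
    x <- ic50s[[nm]]
    pn <- if (nm == neg) NA_real_ else p_vs(x, ic50s[[neg]])
    pp <- if (nm == pos) NA_real_ else p_vs(x, ic50s[[pos]])
    lab <- function(p) {
      if (is.na(p)) "-" else if (p >= alpha) "NS" else sprintf("%.4g", p)
    }
    data.frame(condition = nm, n = length(x), mean_ic50 = mean(x),
               p_vs_negative = pn, p_vs_positive = pp,
               label_vs_negative = lab(pn), label_vs_positive = lab(pp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a dose-response table into viability and GR inputs
#'
#' Collapses a [gen_dose_response()]-dialect table (roles `treated`,
#' `control`, `time_zero`) into per-dose mean counts, viability fractions and
#' GR values.
#'
#' @param data Data frame with columns `role`, `dose_uM`, `count`.
#' @return Data frame with `dose_uM`, `count`, `viability`, `gr`, plus
#'   attributes `x0` and `x_ctrl` (replicate-mean counts).
#' @export
summarize_dose_response <- function(data) {
  need <- c("role", "dose_uM", "count")
  if (!all(need %in% names(data)))
    stop_clonefit("data must have columns %s", paste(need, collapse = ", "))
  x0 <- mean(data$count[data$role == "time_zero"])
  x_ctrl <- mean(data$count[data$role == "control"])
  if (!is.finite(x_ctrl) || x_ctrl <= 0)
    stop_clonefit("control counts missing or non-positive")
  tr <- data[data$role == "treated", ]
  agg <- aggregate(count ~ dose_uM, data = tr, FUN = mean)
  agg <- agg[order(agg$dose_uM), ]
  out <- data.frame(dose_uM = agg$dose_uM, count = agg$count,
                    viability = agg$count / x_ctrl,
                    gr = if (is.finite(x0) && x_ctrl > x0)
                      compute_gr(agg$count, x0, x_ctrl) else NA_real_)
  attr(out, "x0") <- x0
  attr(out, "x_ctrl") <- x_ctrl
  out
}
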