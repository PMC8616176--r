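#' Define a clone growth preset
#'
#' A preset bundles the logistic growth parameters of one single-cell-derived
#' clone together with its measurement noise level, and is the unit the
#' synthetic-data generators consume.
#'
#' @param label Clone label (character scalar).
#' @param fusion_status `"negative"` (drug-sensitive) or `"positive"`
#'   (drug-resistant, efflux-pump expressing).
#' @param r Intrinsic growth rate in 1/h; the doubling time is `log(2)/r`.
#' @param K Carrying capacity in signal units (confluence \% or fluorescence
#'   area).
#' @param x0 Initial signal at seeding; must satisfy `0 < x0 < K`.
#' @param noise_cv Coefficient of variation of the multiplicative measurement
#'   noise (dimensionless, >= 0).
#' @return An object of class `clone_preset`.
#' @seealso [clone_presets()] for the shipped sensitive/resistant pair.
#' @examples
#' p <- clone_preset("clone_A", "negative", r = log(2) / 22, K = 100, x0 = 1)
#' doubling_time(p$r)
#' @export
clone_preset <- function(label, fusion_status = c("negative", "positive"),
                         r, K, x0, noise_cv = 0.05) {
  fusion_status <- match.arg(fusion_status)
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop_clonefit("'label' must be a non-empty string")
  check_number(r, "r", lower = 0, strict_lower = TRUE)
  check_number(K, "K", lower = 0, strict_lower = TRUE)
  check_number(x0, "x0", lower = 0, strict_lower = TRUE)
  check_number(noise_cv, "noise_cv", lower = 0)
  if (x0 >= K) stop_clonefit("preset '%s': need K > x0 > 0", label)
  structure(
    list(label = label, fusion_status = fusion_status,
         r = r, K = K, x0 = x0, noise_cv = noise_cv),
    class = "clone_preset"
  )
}

#' @export
print.clone_preset <- function(x, ...) {
  cat(sprintf("<clone_preset> %s (fusion-%s): r = %.5f /h (t_d = %.1f h), K = %g, x0 = %g, noise CV = %g\n",
              x$label, x$fusion_status, x$r, doubling_time(x$r), x$K, x$x0,
              x$noise_cv))
  invisible(x)
}

#' Doubling time from an intrinsic growth rate
#'
#' @param r Intrinsic growth rate (1/h).
#' @return Doubling time `log(2)/r` in hours.
#' @export
doubling_time <- function(r) log(2) / r

#' Shipped clone presets: a 22 h sensitive and a 44 h resistant clone
#'
#' The default study conditions: a fusion-negative (drug-sensitive) clone with
#' a 22 h population doubling time and a fusion-positive (resistant) clone
#' with a 44 h doubling time, equal carrying capacity and seeding signal, and
#' 5\% multiplicative measurement noise. The resistant clone's 2-fold slower
#' division is the fitness cost of constitutive efflux-pump expression.
#'
#' @param noise_cv Measurement noise CV applied to both presets.
#' @return Named list with elements `fusion_negative` and `fusion_positive`.
#' @export
clone_presets <- function(noise_cv = 0.05) {
  list(
    fusion_negative = clone_preset("fusion_negative", "negative",
                                   r = log(2) / 22, K = 100, x0 = 1,
                                   noise_cv = noise_cv),
    fusion_positive = clone_preset("fusion_positive", "positive",
                                   r = log(2) / 44, K = 100, x0 = 1,
                                   noise_cv = noise_cv)
  )
}

#' Define a two-clone competition preset
#'
#' Couples a sensitive and a resistant [clone_preset()] through Lotka-Volterra
#' competition coefficients. `alpha_sr` is the per-capita crowding effect the
#' resistant clone exerts on the sensitive clone; `alpha_rs` the reverse.
#'
#' @param clone_s Sensitive clone preset.
#' @param clone_r Resistant clone preset.
#' @param alpha_sr Effect of resistant on sensitive (dimensionless, >= 0).
#' @param alpha_rs Effect of sensitive on resistant (dimensionless, >= 0).
#' @param seeding_ratios List of `c(fraction_sensitive, fraction_resistant)`
#'   pairs, each summing to 1.
#' @return An object of class `competition_preset`.
#' @export
competition_preset <- function(clone_s, clone_r, alpha_sr, alpha_rs,
                               seeding_ratios = list(c(0.25, 0.75),
                                                     c(0.50, 0.50),
                                                     c(0.75, 0.25))) {
  stopifnot(inherits(clone_s, "clone_preset"), inherits(clone_r, "clone_preset"))
  check_number(alpha_sr, "alpha_sr", lower = 0)
  check_number(alpha_rs, "alpha_rs", lower = 0)
  for (fr in seeding_ratios) {
    if (length(fr) != 2L || any(fr < 0) || abs(sum(fr) - 1) > 1e-8)
      stop_clonefit("each seeding ratio must be a pair of fractions summing to 1")
  }
  structure(
    list(clone_s = clone_s, clone_r = clone_r,
         alpha_sr = alpha_sr, alpha_rs = alpha_rs,
         seeding_ratios = seeding_ratios),
    class = "competition_preset"
  )
}

#' Shipped competition preset with asymmetric competitive effects
#'
#' The default competition scenario: the shipped 22 h/44 h clone pair with the
#' sensitive clone exerting a 3.5-fold stronger per-capita competitive effect
#' on the resistant clone than vice versa (`alpha_rs = 0.7`,
#' `alpha_sr = 0.2`). Under these coefficients the two clones coexist, with
#' the sensitive clone dominating at carrying capacity.
#'
#' @param noise_cv Measurement noise CV for both clones.
#' @return A [competition_preset()].
#' @export
fusion_competition_preset <- function(noise_cv = 0.05) {
  cp <- clone_presets(noise_cv = noise_cv)
  competition_preset(cp$fusion_negative, cp$fusion_positive,
                     alpha_sr = 0.2, alpha_rs = 0.7)
}

#' @export
print.competition_preset <- function(x, ...) {
  cat(sprintf("<competition_preset> %s vs %s: alpha_sr = %g, alpha_rs = %g (ratio %.2f)\n",
              x$clone_s$label, x$clone_r$label, x$alpha_sr, x$alpha_rs,
              x$alpha_rs / x$alpha_sr))
  cat("  seeding ratios:",
      paste(vapply(x$seeding_ratios,
                   function(fr) sprintf("%g:%g", fr[1], fr[2]), ""),
            collapse = ", "), "\n")
  invisible(x)
}
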