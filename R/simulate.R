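# Synthetic-data generators. Every generator takes an explicit seed, draws
# all randomness under it (restoring the caller's RNG state), and returns the
# generating parameters as a ground-truth sidecar so downstream estimators can
# be scored against known truth.

#' Generate single-clone logistic growth curves
#'
#' Samples noiseless logistic trajectories
#' \eqn{x(t) = K / (1 + ((K - x_0)/x_0) e^{-rt})} at regular intervals and
#' applies multiplicative Gaussian noise (`signal * (1 + eps)`,
#' `eps ~ N(0, cv^2)` truncated at -0.9).
#'
#' @param presets A [clone_preset()] or list of them.
#' @param sampling_interval_h Sampling interval in hours (default 12, the
#'   live-imaging cadence emulated here).
#' @param horizon_h Last sampled time in hours (default 264).
#' @param n_replicates Independent replicate wells per clone (default 4).
#' @param seed Integer seed; identical arguments and seed give byte-identical
#'   output.
#' @return A list with `curves` (data frame: `clone`, `replicate`, `channel`,
#'   `time_h`, `value`) and `truth` (generating parameters keyed by clone).
#' @examples
#' sim <- gen_growth_curves(clone_presets(), n_replicates = 2, seed = 1)
#' head(sim$curves)
#' @export
gen_growth_curves <- function(presets, sampling_interval_h = 12,
                              horizon_h = 264, n_replicates = 4, seed = 1) {
  if (inherits(presets, "clone_preset")) presets <- list(presets)
  if (!length(presets) || !all(vapply(presets, inherits, TRUE, "clone_preset")))
    stop_clonefit("'presets' must be clone_preset objects")
  check_number(sampling_interval_h, "sampling_interval_h", 0, strict_lower = TRUE)
  check_number(horizon_h, "horizon_h", 0, strict_lower = TRUE)
  if (horizon_h < 2 * sampling_interval_h)
    stop_clonefit("'horizon_h' must cover at least two sampling intervals")
  n_replicates <- as.integer(check_number(n_replicates, "n_replicates", 1))

  times <- seq(0, horizon_h, by = sampling_interval_h)
  curves <- with_seed(seed, {
    do.call(rbind, lapply(presets, function(p) {
      mu <- logistic_curve(times, p$r, p$K, p$x0)
      do.call(rbind, lapply(seq_len(n_replicates), function(rep) {
        data.frame(clone = p$label, replicate = rep, channel = "phase",
                   time_h = times, value = mult_noise(mu, p$noise_cv),
                   stringsAsFactors = FALSE)
      }))
    }))
  })
  rownames(curves) <- NULL
  truth <- lapply(presets, unclass)
  names(truth) <- vapply(presets, `[[`, "", "label")
  list(curves = curves,
       truth = list(kind = "growth_curves", clones = truth,
                    sampling_interval_h = sampling_interval_h,
                    horizon_h = horizon_h, n_replicates = n_replicates,
                    seed = seed))
}

#' Generate mono- and co-culture curves under Lotka-Volterra competition
#'
#' Monocultures of the sensitive and resistant clone plus co-cultures at each
#' seeding ratio of the preset, generated by numerically integrating the
#' two-clone competitive Lotka-Volterra system (see [simulate_lv()]) and
#' adding multiplicative noise. The two populations are read out on separate
#' fluorescence channels (`yellow` = sensitive, `red` = resistant). A
#' co-culture seeded at ratio (f_s, f_r) starts at `f_s * N0` and `f_r * N0`
#' with `N0` the mean of the two monoculture seeding signals, i.e. the same
#' total seeding density as a monoculture.
#'
#' @param preset A [competition_preset()].
#' @inheritParams gen_growth_curves
#' @return A list with `curves` (columns `clone`, `replicate`, `channel`,
#'   `time_h`, `value`, plus `culture` in `{mono_s, mono_r, coculture}` and
#'   `frac_s`, the seeded sensitive fraction) and `truth`.
#' @export
gen_coculture <- function(preset, sampling_interval_h = 12, horizon_h = 264,
                          n_replicates = 4, seed = 1) {
  stopifnot(inherits(preset, "competition_preset"))
  check_number(sampling_interval_h, "sampling_interval_h", 0, strict_lower = TRUE)
  if (horizon_h < 2 * sampling_interval_h)
    stop_clonefit("'horizon_h' must cover at least two sampling intervals")
  n_replicates <- as.integer(check_number(n_replicates, "n_replicates", 1))

  s <- preset$clone_s
  r <- preset$clone_r
  params <- lv_params(r_s = s$r, r_r = r$r, K_s = s$K, K_r = r$K,
                      alpha_sr = preset$alpha_sr, alpha_rs = preset$alpha_rs)
  times <- seq(0, horizon_h, by = sampling_interval_h)
  n0 <- (s$x0 + r$x0) / 2

  conditions <- list(
    list(clone = s$label, culture = "mono_s", frac_s = 1,
         init = c(s$x0, 0)),
    list(clone = r$label, culture = "mono_r", frac_s = 0,
         init = c(0, r$x0))
  )
  for (fr in preset$seeding_ratios) {
    conditions[[length(conditions) + 1L]] <- list(
      clone = sprintf("mix_%02.0f_%02.0f", 100 * fr[1], 100 * fr[2]),
      culture = "coculture", frac_s = fr[1],
      init = c(fr[1] * n0, fr[2] * n0))
  }

  curves <- with_seed(seed, {
    do.call(rbind, lapply(conditions, function(cond) {
      # generation uses tighter-than-default integration so the noiseless
      # decoupled case matches the closed-form logistic to ~1e-8 absolute
      traj <- simulate_lv(params, initial = cond$init, times = times,
                          rtol = 1e-11, atol = 1e-13)
      do.call(rbind, lapply(seq_len(n_replicates), function(rep) {
        rows <- list()
        if (cond$init[1] > 0 || cond$culture == "mono_s")
          rows$s <- data.frame(clone = cond$clone, replicate = rep,
                               channel = "yellow", time_h = times,
                               value = mult_noise(traj$x_s, s$noise_cv),
                               culture = cond$culture, frac_s = cond$frac_s,
                               stringsAsFactors = FALSE)
        if (cond$init[2] > 0 || cond$culture == "mono_r")
          rows$r <- data.frame(clone = cond$clone, replicate = rep,
                               channel = "red", time_h = times,
                               value = mult_noise(traj$x_r, r$noise_cv),
                               culture = cond$culture, frac_s = cond$frac_s,
                               stringsAsFactors = FALSE)
        do.call(rbind, rows)
      }))
    }))
  })
  rownames(curves) <- NULL
  list(curves = curves,
       truth = list(kind = "coculture",
                    clone_s = unclass(s), clone_r = unclass(r),
                    alpha_sr = preset$alpha_sr, alpha_rs = preset$alpha_rs,
                    seeding_ratios = preset$seeding_ratios,
                    sampling_interval_h = sampling_interval_h,
                    horizon_h = horizon_h, n_replicates = n_replicates,
                    seed = seed))
}

#' Specify a multi-plate 384-well viability screen
#'
#' @param n_compounds Number of library compounds.
#' @param doses Dose ladder in µM (default the 3-point primary-screen ladder
#'   5, 0.5, 0.05 µM; use `c(10, 5, 2.25, 0.5, 0.225, 0.05)` for the 6-point
#'   validation ladder).
#' @param cell_lines Cell line labels; the hit rules require every compound in
#'   every line.
#' @param n_control_wells Vehicle (DMSO) control wells per plate (>= 8).
#' @param baseline_count Expected control cell count per well.
#' @param batch_sdlog Log-SD of the per-plate lognormal batch factor.
#' @param batch_factors Optional fixed per-plate batch factors (recycled over
#'   plates), overriding the random draw.
#' @param count_noise_cv Per-well multiplicative count noise CV.
#' @param planted_hits Named list mapping compound id to true viability
#'   fraction(s), a scalar or one value per dose; unlisted compounds have true
#'   viability 1 at all doses.
#' @return An object of class `screen_spec`.
#' @export
screen_spec <- function(n_compounds = 100,
                        doses = c(5, 0.5, 0.05),
                        cell_lines = c("clone_D", "clone_E",
                                       "clone_9", "clone_18B"),
                        n_control_wells = 16,
                        baseline_count = 1000,
                        batch_sdlog = 0.15,
                        batch_factors = NULL,
                        count_noise_cv = 0.1,
                        planted_hits = list()) {
  n_compounds <- as.integer(check_number(n_compounds, "n_compounds", 1))
  if (any(doses <= 0) || anyDuplicated(doses))
    stop_clonefit("'doses' must be unique and strictly positive")
  if (n_control_wells < 8)
    stop_clonefit("every plate needs at least 8 negative-control wells")
  check_number(baseline_count, "baseline_count", 0, strict_lower = TRUE)
  check_number(count_noise_cv, "count_noise_cv", 0)
  compounds <- sprintf("cmpd_%03d", seq_len(n_compounds))
  if (length(planted_hits)) {
    if (is.null(names(planted_hits)) || !all(names(planted_hits) %in% compounds))
      stop_clonefit("'planted_hits' names must be compound ids (cmpd_###)")
    ok <- vapply(planted_hits, function(v)
      length(v) %in% c(1L, length(doses)) && all(v >= 0 & v <= 1), TRUE)
    if (!all(ok))
      stop_clonefit("planted viabilities must lie in [0, 1], one per dose or a scalar")
  }
  structure(
    list(n_compounds = n_compounds, compounds = compounds, doses = doses,
         cell_lines = cell_lines, n_control_wells = n_control_wells,
         baseline_count = baseline_count, batch_sdlog = batch_sdlog,
         batch_factors = batch_factors, count_noise_cv = count_noise_cv,
         planted_hits = planted_hits),
    class = "screen_spec"
  )
}

#' Generate a 384-well screen plate table
#'
#' Per-well counts are `baseline * plate batch factor * true viability *
#' (1 + noise)`; negative-control wells have true viability 1. Each cell line
#' occupies its own plate(s); compound wells fill plates of 384 wells minus
#' the control wells.
#'
#' @param spec A [screen_spec()].
#' @param seed Integer seed.
#' @return A list with `wells` (data frame: `plate_id`, `well`, `row`, `col`,
#'   `role`, `compound`, `dose_uM`, `cell_line`, `count`) and `truth`.
#' @export
gen_screen <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "screen_spec"))
  per_plate_cap <- 384L - spec$n_control_wells
  jobs <- expand.grid(compound = spec$compounds, dose_uM = spec$doses,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_plates_per_line <- ceiling(nrow(jobs) / per_plate_cap)
  viab <- function(compound, dose) {
    v <- spec$planted_hits[[compound]]
    if (is.null(v)) return(1)
    if (length(v) == 1L) v else v[match(dose, spec$doses)]
  }

  wells <- with_seed(seed, {
    out <- list()
    plate_no <- 0L
    for (line in spec$cell_lines) {
      for (p in seq_len(n_plates_per_line)) {
        plate_no <- plate_no + 1L
        plate_id <- sprintf("plate_%02d", plate_no)
        batch <- if (!is.null(spec$batch_factors)) {
          spec$batch_factors[((plate_no - 1L) %% length(spec$batch_factors)) + 1L]
        } else {
          rlnorm(1, 0, spec$batch_sdlog)
        }
        idx <- seq((p - 1L) * per_plate_cap + 1L,
                   min(p * per_plate_cap, nrow(jobs)))
        plate_jobs <- jobs[idx, , drop = FALSE]
        n_wells <- nrow(plate_jobs) + spec$n_control_wells
        pos <- seq_len(n_wells)
        row_i <- ((pos - 1L) %% 16L) + 1L
        col_i <- ((pos - 1L) %/% 16L) + 1L
        ctrl <- pos <= spec$n_control_wells   # first column(s) hold controls
        true_v <- c(rep(1, spec$n_control_wells),
                    mapply(viab, plate_jobs$compound, plate_jobs$dose_uM))
        counts <- mult_noise(spec$baseline_count * batch * true_v,
                             spec$count_noise_cv)
        out[[plate_id]] <- data.frame(
          plate_id = plate_id,
          well = sprintf("%s%02d", LETTERS[row_i], col_i),
          row = row_i, col = col_i,
          role = ifelse(ctrl, "negative_control", "compound"),
          compound = c(rep(NA_character_, spec$n_control_wells),
                       plate_jobs$compound),
          dose_uM = c(rep(NA_real_, spec$n_control_wells),
                      plate_jobs$dose_uM),
          cell_line = line, count = counts,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  rownames(wells) <- NULL
  list(wells = wells,
       truth = list(kind = "screen", spec = unclass(spec), seed = seed))
}

#' Generate a viability dose-response table, optionally for a clonal mixture
#'
#' Counts are proportional to the independent-action mixture survival
#' `(1 - f) * S_neg(d) + f * S_pos(d)` where each `S` is a four-parameter
#' logistic survival curve and `f` is the fraction of resistant
#' (fusion-positive) cells. The table carries vehicle-control rows
#' (`role = "control"`) and time-of-treatment rows (`role = "time_zero"`) so
#' that GR metrics can be computed downstream.
#'
#' @param params_neg Named list/vector with `top`, `bottom`, `hill`, `ec50`
#'   for the sensitive clone's survival curve (ec50 in the dose units used).
#' @param params_pos Same for the resistant clone; may be `NULL` when `f = 0`.
#' @param doses Dose ladder (> 0).
#' @param fraction_positive Mixture fraction `f` in `[0, 1]`.
#' @param n_replicates Replicate wells per dose.
#' @param x0_count Cell count at time of treatment.
#' @param control_fold Fold growth of vehicle controls over the treatment
#'   window (e.g. 8 for three divisions in 72 h).
#' @param noise_cv Count noise CV.
#' @param seed Integer seed.
#' @return A list with `data` (data frame: `id`, `role`, `dose_uM`,
#'   `replicate`, `count`) and `truth`.
#' @export
gen_dose_response <- function(params_neg, params_pos = NULL, doses,
                              fraction_positive = 0, n_replicates = 3,
                              x0_count = 1000, control_fold = 8,
                              noise_cv = 0.05, seed = 1) {
  f <- fraction_positive
  check_number(f, "fraction_positive", 0, 1)
  if (any(doses <= 0)) stop_clonefit("'doses' must be strictly positive")
  pn <- validate_4pl_params(params_neg, "params_neg")
  pp <- if (f > 0) validate_4pl_params(params_pos, "params_pos") else pn
  n_replicates <- as.integer(check_number(n_replicates, "n_replicates", 1))

  surv <- function(p, d) p$bottom + (p$top - p$bottom) / (1 + (d / p$ec50)^p$hill)
  s_mix <- (1 - f) * surv(pn, doses) + f * surv(pp, doses)
  ctrl_count <- x0_count * control_fold

  data <- with_seed(seed, {
    treated <- do.call(rbind, lapply(seq_len(n_replicates), function(rep) {
      data.frame(id = "mixture", role = "treated", dose_uM = doses,
                 replicate = rep,
                 count = mult_noise(ctrl_count * s_mix, noise_cv),
                 stringsAsFactors = FALSE)
    }))
    control <- data.frame(id = "mixture", role = "control", dose_uM = NA_real_,
                          replicate = seq_len(n_replicates),
                          count = mult_noise(rep(ctrl_count, n_replicates),
                                             noise_cv),
                          stringsAsFactors = FALSE)
    t0 <- data.frame(id = "mixture", role = "time_zero", dose_uM = NA_real_,
                     replicate = seq_len(n_replicates),
                     count = mult_noise(rep(x0_count, n_replicates), noise_cv),
                     stringsAsFactors = FALSE)
    rbind(treated, control, t0)
  })
  rownames(data) <- NULL
  list(data = data,
       truth = list(kind = "dose_response", params_neg = pn, params_pos = pp,
                    fraction_positive = f, doses = doses,
                    x0_count = x0_count, control_fold = control_fold,
                    noise_cv = noise_cv, seed = seed))
}

validate_4pl_params <- function(p, name) {
  p <- as.list(p)
  need <- c("top", "bottom", "hill", "ec50")
  if (!all(need %in% names(p)))
    stop_clonefit("'%s' must provide top, bottom, hill, ec50", name)
  p <- p[need]
  if (p$ec50 <= 0 || p$hill <= 0 || p$bottom > p$top)
    stop_clonefit("'%s': need ec50 > 0, hill > 0, bottom <= top", name)
  p
}

#' Specify a synthetic morphology feature table
#'
#' @param n_cells_per_group Cells per group.
#' @param n_features Total feature count.
#' @param n_inactive Number of near-constant (inactive) features.
#' @param corr_blocks List of `c(size, r)` pairs: blocks of mutually
#'   correlated features with target pairwise Pearson r.
#' @param group_shift Per-feature shift of the non-reference group, in
#'   reference-MAD units; scalar or length `n_features`.
#' @param groups Two group labels; the first is the reference population.
#' @return An object of class `morph_spec`.
#' @export
morph_spec <- function(n_cells_per_group = 500, n_features = 50,
                       n_inactive = 5, corr_blocks = list(),
                       group_shift = 0,
                       groups = c("fusion_negative", "fusion_positive")) {
  n_features <- as.integer(check_number(n_features, "n_features", 2))
  n_inactive <- as.integer(check_number(n_inactive, "n_inactive", 0))
  block_sizes <- vapply(corr_blocks, function(b) as.integer(b[1]), 1L)
  block_r <- vapply(corr_blocks, function(b) b[2], 1)
  if (any(abs(block_r) > 1))
    stop_clonefit("correlation block target |r| > 1 is infeasible")
  if (any(block_sizes < 2))
    stop_clonefit("correlation blocks need at least 2 features")
  if (n_inactive + sum(block_sizes) > n_features)
    stop_clonefit("n_inactive + correlated block sizes exceed n_features")
  if (!length(group_shift) %in% c(1L, n_features))
    stop_clonefit("'group_shift' must be scalar or one value per feature")
  structure(
    list(n_cells_per_group = as.integer(n_cells_per_group),
         n_features = n_features, n_inactive = n_inactive,
         corr_blocks = corr_blocks, group_shift = group_shift,
         groups = groups),
    class = "morph_spec"
  )
}

#' Generate a per-cell morphology feature table
#'
#' Active features are unit-scale Gaussians; correlated blocks are built from
#' a shared factor so every within-block pair has the target Pearson r;
#' inactive features are constant up to numerical jitter (SD 1e-8 of the
#' reference scale). The non-reference group is shifted by `group_shift`
#' reference-MAD units per feature. Feature layout: correlated blocks first,
#' then independent active features, then inactive features.
#'
#' @param spec A [morph_spec()].
#' @param seed Integer seed.
#' @return A list with `features` (data frame: `cell_id`, `group`,
#'   `feat_001` ...) and `truth`.
#' @export
gen_morphology <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "morph_spec"))
  n <- spec$n_cells_per_group
  p <- spec$n_features
  shift <- rep(spec$group_shift, length.out = p)
  block_sizes <- vapply(spec$corr_blocks, function(b) as.integer(b[1]), 1L)

  features <- with_seed(seed, {
    draw_group <- function(group, shifted) {
      x <- matrix(0, n, p)
      j <- 0L
      for (b in spec$corr_blocks) {
        size <- as.integer(b[1]); r <- b[2]
        common <- rnorm(n)
        for (k in seq_len(size)) {
          j <- j + 1L
          x[, j] <- sqrt(abs(r)) * sign(r)^(k > 1) * common +
            sqrt(1 - abs(r)) * rnorm(n)
        }
      }
      n_indep <- p - sum(block_sizes) - spec$n_inactive
      if (n_indep > 0) {
        x[, j + seq_len(n_indep)] <- rnorm(n * n_indep)
        j <- j + n_indep
      }
      if (spec$n_inactive > 0)
        x[, j + seq_len(spec$n_inactive)] <- 1 + rnorm(n * spec$n_inactive,
                                                       sd = 1e-8)
      if (shifted) x <- sweep(x, 2, shift, "+")
      x
    }
    ref <- draw_group(spec$groups[1], shifted = FALSE)
    alt <- draw_group(spec$groups[2], shifted = TRUE)
    mat <- rbind(ref, alt)
    colnames(mat) <- sprintf("feat_%03d", seq_len(p))
    data.frame(cell_id = sprintf("cell_%05d", seq_len(2L * n)),
               group = rep(spec$groups, each = n),
               mat, stringsAsFactors = FALSE)
  })
  list(features = features,
       truth = list(kind = "morphology", spec = unclass(spec),
                    group_shift = shift, seed = seed))
}
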