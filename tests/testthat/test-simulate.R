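# Synthetic-data generators: determinism, noiseless oracles, sidecars.

test_that("growth curves are deterministic per seed and leave the RNG alone", {
  sim1 <- gen_growth_curves(clone_presets(), n_replicates = 2, seed = 5)
  sim2 <- gen_growth_curves(clone_presets(), n_replicates = 2, seed = 5)
  sim3 <- gen_growth_curves(clone_presets(), n_replicates = 2, seed = 6)
  expect_identical(sim1$curves, sim2$curves)
  expect_false(identical(sim1$curves, sim3$curves))

  set.seed(99)
  before <- runif(3)
  set.seed(99)
  invisible(gen_growth_curves(clone_presets(), seed = 1))
  expect_identical(runif(3), before)
})

test_that("noiseless growth curves equal the closed-form logistic exactly", {
  p <- clone_preset("c", "negative", r = 0.02, K = 80, x0 = 2, noise_cv = 0)
  sim <- gen_growth_curves(p, sampling_interval_h = 24, horizon_h = 240,
                           n_replicates = 1, seed = 123)
  expect_equal(sim$curves$value,
               logistic_curve(sim$curves$time_h, 0.02, 80, 2),
               tolerance = 1e-12)
})

test_that("shipped presets encode 22 h and 44 h doubling times", {
  cp <- clone_presets(noise_cv = 0)
  expect_equal(doubling_time(cp$fusion_negative$r), 22)
  expect_equal(doubling_time(cp$fusion_positive$r), 44)
  sim <- gen_growth_curves(cp, n_replicates = 1, seed = 1)
  for (clone in c("fusion_negative", "fusion_positive")) {
    d <- sim$curves[sim$curves$clone == clone, ]
    fit <- fit_logistic(d$time_h, d$value)
    expect_equal(fit$t_d, if (clone == "fusion_negative") 22 else 44,
                 tolerance = 1e-6)
  }
})

test_that("logistic signal crosses 50 at ~145.8 h when K = 2x threshold", {
  # analytic: t50 = ln((K - x0)/x0)/r = ln(99)/0.03151
  expect_equal(logistic_curve(log(99) / 0.03151, 0.03151, 100, 1), 50,
               tolerance = 1e-10)
  expect_equal(log(99) / 0.03151, 145.8, tolerance = 0.05)
})

test_that("generator validates preset parameters", {
  expect_error(clone_preset("bad", "negative", r = -1, K = 100, x0 = 1),
               "valid range")
  expect_error(clone_preset("bad", "negative", r = 0.03, K = 1, x0 = 2),
               "K > x0")
  expect_error(gen_growth_curves(clone_presets(), sampling_interval_h = 200,
                                 horizon_h = 264),
               "two sampling intervals")
})

test_that("co-culture channels equal monoculture logistics when alphas are 0", {
  cp <- clone_presets(noise_cv = 0)
  pres <- competition_preset(cp$fusion_negative, cp$fusion_positive, 0, 0,
                             seeding_ratios = list(c(0.5, 0.5)))
  sim <- gen_coculture(pres, n_replicates = 1, seed = 1)
  mix <- sim$curves[sim$curves$culture == "coculture", ]
  for (ch in c("yellow", "red")) {
    d <- mix[mix$channel == ch, ]
    pr <- if (ch == "yellow") cp$fusion_negative else cp$fusion_positive
    expect_lt(max(abs(d$value - logistic_curve(d$time_h, pr$r, pr$K, 0.5))),
              1e-8)
  }
})

test_that("shipped competition preset lets the sensitive clone dominate late", {
  sim <- gen_coculture(fusion_competition_preset(noise_cv = 0),
                       n_replicates = 1, seed = 1)
  mix <- sim$curves[sim$curves$culture == "coculture", ]
  for (cond in unique(mix$clone)) {
    d <- mix[mix$clone == cond, ]
    t_end <- max(d$time_h)
    s_end <- d$value[d$time_h == t_end & d$channel == "yellow"]
    r_end <- d$value[d$time_h == t_end & d$channel == "red"]
    expect_gt(s_end, r_end)
  }
})

test_that("screen batch factors scale raw counts but not fold changes", {
  sp2 <- screen_spec(n_compounds = 10, count_noise_cv = 0,
                     batch_factors = c(2, 1, 1, 1))
  sp1 <- screen_spec(n_compounds = 10, count_noise_cv = 0,
                     batch_factors = c(1, 1, 1, 1))
  w2 <- gen_screen(sp2, seed = 1)$wells
  w1 <- gen_screen(sp1, seed = 1)$wells
  ctrl2 <- w2[w2$role == "negative_control", ]
  expect_equal(median(ctrl2$count[ctrl2$plate_id == "plate_01"]),
               2 * median(ctrl2$count[ctrl2$plate_id == "plate_02"]))
  expect_equal(normalize_plates(w2)$wells$fold_change,
               normalize_plates(w1)$wells$fold_change, tolerance = 1e-12)
})

test_that("screen spec validation rejects degenerate layouts", {
  expect_error(screen_spec(n_control_wells = 4), "at least 8")
  expect_error(screen_spec(doses = c(5, -1)), "strictly positive")
  expect_error(screen_spec(planted_hits = list(nope = 0.3)), "compound ids")
})

test_that("dose-response mixtures collapse to pure clones at f = 0 and 1", {
  pn <- list(top = 1, bottom = 0, hill = 1, ec50 = 10)
  pp <- list(top = 1, bottom = 0, hill = 1, ec50 = 100)
  doses <- log_dose_grid()
  pure_neg <- gen_dose_response(pn, pp, doses, fraction_positive = 0, seed = 3)
  mix0 <- gen_dose_response(pn, pp, doses, fraction_positive = 0, seed = 3)
  expect_identical(pure_neg$data, mix0$data)
  pure_pos <- gen_dose_response(pp, NULL, doses, fraction_positive = 0,
                                seed = 3)
  mix1 <- gen_dose_response(pn, pp, doses, fraction_positive = 1, seed = 3)
  expect_equal(mix1$data$count, pure_pos$data$count, tolerance = 1e-12)
  expect_error(gen_dose_response(pn, pp, doses, fraction_positive = 1.2),
               "valid range")
})

test_that("a 50:50 hill-1 mixture crosses half-control at 10*sqrt(10)", {
  pn <- list(top = 1, bottom = 0, hill = 1, ec50 = 10)
  pp <- list(top = 1, bottom = 0, hill = 1, ec50 = 100)
  doses <- log_dose_grid(0.1, 10000, 41)
  sim <- gen_dose_response(pn, pp, doses, fraction_positive = 0.5,
                           noise_cv = 0, seed = 1)
  sdr <- summarize_dose_response(sim$data)
  crossing <- approx(sdr$viability, log10(sdr$dose_uM), xout = 0.5)$y
  expect_equal(10^crossing, 10 * sqrt(10), tolerance = 0.02)
})

test_that("morphology correlation blocks hit their target Pearson r", {
  spec <- morph_spec(n_cells_per_group = 500, n_features = 10,
                     n_inactive = 0, corr_blocks = list(c(2, 0.95)))
  feats <- gen_morphology(spec, seed = 4)$features
  r <- cor(feats$feat_001, feats$feat_002)
  expect_gt(r, 0.90)
  expect_lt(r, 0.99)
  expect_error(morph_spec(corr_blocks = list(c(2, 1.5))), "infeasible")
  expect_error(morph_spec(n_features = 10, n_inactive = 9,
                          corr_blocks = list(c(2, 0.5))),
               "exceed n_features")
})

test_that("inactive morphology features are near-constant", {
  spec <- morph_spec(n_cells_per_group = 100, n_features = 6, n_inactive = 2)
  feats <- gen_morphology(spec, seed = 1)$features
  expect_lt(sd(feats$feat_005), 1e-6)
  expect_lt(sd(feats$feat_006), 1e-6)
  expect_gt(sd(feats$feat_001), 0.5)
})

test_that("ground-truth sidecars regenerate identical data", {
  sim <- gen_coculture(fusion_competition_preset(), n_replicates = 2,
                       seed = 11)
  tr <- sim$truth
  preset <- competition_preset(
    do.call(clone_preset, tr$clone_s[c("label", "fusion_status", "r", "K",
                                       "x0", "noise_cv")]),
    do.call(clone_preset, tr$clone_r[c("label", "fusion_status", "r", "K",
                                       "x0", "noise_cv")]),
    alpha_sr = tr$alpha_sr, alpha_rs = tr$alpha_rs,
    seeding_ratios = tr$seeding_ratios)
  sim2 <- gen_coculture(preset, tr$sampling_interval_h, tr$horizon_h,
                        tr$n_replicates, tr$seed)
  expect_identical(sim$curves, sim2$curves)
})
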