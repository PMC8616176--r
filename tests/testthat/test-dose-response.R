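# 4PL viability fits, GR metrics, mixture prediction, group comparisons.

test_that("exact 4PL data are recovered to 1e-6 relative", {
  d <- log_dose_grid()
  v <- fourpl_values(d, top = 1, bottom = 0, hill = 1, ec50 = 10)
  fit <- fit_4pl(d, v)
  expect_true(fit$converged)
  expect_equal(fit$ec50_rel, 10, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  expect_equal(fit$top, 1, tolerance = 1e-6)
  expect_lt(abs(fit$bottom), 1e-6)
  expect_equal(fit$ic50_abs, 10, tolerance = 0.01)

  v2 <- fourpl_values(d, top = 0.95, bottom = 0.1, hill = 2, ec50 = 3)
  fit2 <- fit_4pl(d, v2)
  expect_equal(coef(fit2), c(top = 0.95, bottom = 0.1, hill = 2,
                             ec50_rel = 3), tolerance = 1e-6)
  # absolute IC50 differs from the midpoint when top != 1 or bottom != 0
  expect_equal(predict(fit2, fit2$ic50_abs), 0.5, tolerance = 1e-6)
})

test_that("a curve that never reaches 50% leaves the IC50 undefined", {
  d <- log_dose_grid()
  fit <- fit_4pl(d, fourpl_values(d, top = 0.98, bottom = 0.92, hill = 1,
                                  ec50 = 10))
  expect_false(fit$ic50_defined)
  expect_true(is.na(fit$ic50_abs))
})

test_that("viability increasing with dose is reported as non-converged", {
  d <- log_dose_grid()
  fit <- fit_4pl(d, 0.2 + 0.8 * (d / 10) / (1 + d / 10))
  expect_false(fit$converged)
})

test_that("fold_resistance is the ratio of arithmetic group means", {
  expect_equal(fold_resistance(c(2, 4), c(1, 2)), 2)
  expect_equal(fold_resistance(5, 5), 1)
  expect_warning(fr <- fold_resistance(c(10, NA), c(2, 3)), "undefined")
  expect_equal(fr, 4)
  expect_error(fold_resistance(numeric(0), 1), "at least one")
})

test_that("compute_gr matches its closed form and boundary identities", {
  expect_equal(compute_gr(200, 100, 800), 2^(1 / 3) - 1, tolerance = 1e-10)
  expect_equal(compute_gr(200, 100, 800), 0.2599, tolerance = 1e-4)
  expect_equal(compute_gr(800, 100, 800), 1)   # no drug effect
  expect_equal(compute_gr(100, 100, 800), 0)   # complete cytostasis
  expect_error(compute_gr(200, 100, 90), "GR undefined")
})

test_that("GR stays in (-1, 1] and is monotone in the treated count", {
  set.seed(7)
  x0 <- 100; x_ctrl <- 900
  x_c <- sort(runif(50, 1e-3, x_ctrl))
  gr <- compute_gr(x_c, x0, x_ctrl)
  expect_true(all(gr > -1 & gr <= 1))
  expect_true(all(diff(gr) > 0))
})

test_that("exact GR curves yield GR50 = GEC50 when GR_inf = 0", {
  d <- log_dose_grid(0.001, 10, 9)
  gr <- 0 + (1 - 0) / (1 + (d / 0.1))
  fit <- fit_gr_curve(d, gr)
  expect_false(fit$utbd)
  expect_equal(fit$gr50, 0.1, tolerance = 1e-6)
})

test_that("flat GR curves are flagged UTBD, not errors", {
  d <- c(0.05, 0.225, 0.5, 2.25, 5, 10)
  fit <- fit_gr_curve(d, 1 + c(1, -1, 1, -1, 1, -1) * 1e-4)
  expect_true(fit$utbd)
  expect_match(fit$utbd_reason, "flat")
  expect_true(is.na(fit$gr50))
})

test_that("GR50 is division-rate invariant while IC50 is not", {
  d <- log_dose_grid(0.01, 10, 13)
  fast <- per_division_counts(d, doubling_h = 22)
  slow <- per_division_counts(d, doubling_h = 44)

  gr_fast <- compute_gr(fast$x_c, fast$x0, fast$x_ctrl)
  gr_slow <- compute_gr(slow$x_c, slow$x0, slow$x_ctrl)
  expect_equal(gr_fast, fast$gr_true, tolerance = 1e-10)
  expect_equal(gr_fast, gr_slow, tolerance = 1e-10)

  g50_fast <- fit_gr_curve(d, gr_fast)$gr50
  g50_slow <- fit_gr_curve(d, gr_slow)$gr50
  expect_equal(g50_fast, g50_slow, tolerance = 0.05)

  ic_fast <- fit_4pl(d, fast$x_c / fast$x_ctrl)$ic50_abs
  ic_slow <- fit_4pl(d, slow$x_c / slow$x_ctrl)$ic50_abs
  expect_gt(abs(ic_fast - ic_slow) / ic_slow, 0.2)
  expect_lt(ic_fast, ic_slow)   # faster divider looks more sensitive
})

test_that("mixture IC50 matches the algebraic value and is monotone in f", {
  d <- log_dose_grid()
  fit_neg <- fit_4pl(d, fourpl_values(d, ec50 = 10))
  fit_pos <- fit_4pl(d, fourpl_values(d, ec50 = 100))
  mix <- predict_mixture_ic50(fit_neg, fit_pos, 0.5)
  expect_true(mix$defined)
  expect_equal(mix$ic50, 10 * sqrt(10), tolerance = 0.05)

  expect_equal(predict_mixture_ic50(fit_neg, fit_pos, 0)$ic50,
               fit_neg$ic50_abs, tolerance = 1e-4)
  expect_equal(predict_mixture_ic50(fit_neg, fit_pos, 1)$ic50,
               fit_pos$ic50_abs, tolerance = 1e-4)
  ic50s <- vapply(seq(0, 1, 0.25), function(f)
    predict_mixture_ic50(fit_neg, fit_pos, f)$ic50, 1)
  expect_true(all(diff(ic50s) > 0))
  # 75% resistant exceeds the pure-sensitive IC50 under independent action
  expect_gt(ic50s[4], fit_neg$ic50_abs)
})

test_that("compare_group_ic50 reproduces Table-style NS patterns", {
  ic50s <- list(neg_100 = c(0.30, 0.28, 0.32),
                pos_100 = c(1.05, 1.20, 0.95),
                mix_50_50 = c(0.31, 0.29, 0.33))
  out <- compare_group_ic50(ic50s)
  mix <- out[out$condition == "mix_50_50", ]
  expect_identical(mix$label_vs_negative, "NS")
  expect_lt(mix$p_vs_positive, 0.05)
  pos <- out[out$condition == "pos_100", ]
  expect_lt(pos$p_vs_negative, 0.05)

  same <- compare_group_ic50(list(neg_100 = c(1, 2, 3),
                                  pos_100 = c(1, 2, 3)))
  expect_identical(same$label_vs_negative[2], "NS")
  expect_error(compare_group_ic50(list(neg_100 = c(1, 2), pos_100 = 1:3)),
               "at least 3")
})

test_that("two non-overlapping groups of 3 separate at p < 0.05", {
  out <- compare_group_ic50(list(neg_100 = c(1.0, 1.1, 0.9),
                                 pos_100 = c(5.0, 5.2, 4.8)))
  expect_lt(out$p_vs_negative[out$condition == "pos_100"], 0.05)
  # oracle: closed-form pooled t for these values
  a <- c(1.0, 1.1, 0.9); b <- c(5.0, 5.2, 4.8)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 4
  t_manual <- (mean(b) - mean(a)) / sqrt(sp2 * (2 / 3))
  p_manual <- 2 * pt(-abs(t_manual), df = 4)
  expect_equal(out$p_vs_negative[out$condition == "pos_100"], p_manual,
               tolerance = 1e-10)
})

test_that("summarize_dose_response produces viability and GR per dose", {
  pn <- list(top = 1, bottom = 0, hill = 1, ec50 = 10)
  sim <- gen_dose_response(pn, NULL, log_dose_grid(), noise_cv = 0, seed = 1)
  sdr <- summarize_dose_response(sim$data)
  expect_equal(attr(sdr, "x0"), 1000)
  expect_equal(attr(sdr, "x_ctrl"), 8000)
  expect_equal(sdr$viability, fourpl_values(sort(log_dose_grid()), ec50 = 10),
               tolerance = 1e-10)
  expect_true(all(sdr$gr <= 1 & sdr$gr > -1))
})
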