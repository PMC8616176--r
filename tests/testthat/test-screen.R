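# Screen normalization, robust Z-scores and hit calling.

test_that("fold change divides by the per-plate control median", {
  wells <- data.frame(
    plate_id = "p1",
    role = c(rep("negative_control", 4), "compound"),
    compound = c(rep(NA, 4), "cmpd_001"),
    dose_uM = c(rep(NA, 4), 5),
    cell_line = "line_1",
    count = c(1000, 1100, 900, 1000, 450))
  norm <- normalize_plates(wells)
  expect_equal(norm$plate_stats$ctrl_median, 1000)
  expect_equal(norm$wells$fold_change[5], 0.45)
  # wells at the control median normalize to exactly 1, and the plate's
  # control fold-change median is 1 by construction
  expect_equal(norm$wells$fold_change[1], 1)
  expect_equal(median(norm$wells$fold_change[norm$wells$role ==
                                               "negative_control"]), 1)
})

test_that("plates without controls are rejected by name", {
  wells <- data.frame(plate_id = c("p1", "p2"), role = "compound",
                      count = c(10, 20))
  expect_error(normalize_plates(wells), "p1")
})

test_that("robust_z matches the hand-computed MAD standardization", {
  x <- rep(c(0.5, 0.8, 1.0, 1.1, 1.2), 2)   # median 1.0, raw MAD 0.2
  rz <- robust_z(x)
  expect_identical(rz$method, "mad")
  expect_equal(rz$scale, 1.4826 * 0.2)
  expect_equal(rz$z[1], -1.686, tolerance = 0.001)
  expect_equal(rz$z[x == 1.0], c(0, 0))
})

test_that("zero MAD falls back to the SD with a flag", {
  x <- c(rep(1, 95), rep(0.2, 5))
  rz <- robust_z(x)
  expect_identical(rz$method, "sd_fallback")
  expect_gt(rz$scale, 0)
  rz0 <- robust_z(rep(3, 12))
  expect_identical(rz0$method, "degenerate")
  expect_true(all(rz0$z == 0))
  expect_error(robust_z(1:5), "at least 10")
})

test_that("primary hits require <50% of control in every cell line", {
  lines <- sprintf("line_%d", 1:4)
  doses <- c(5, 0.5, 0.05)
  fold <- array(0.9, dim = c(3, 3, 4))
  fold[1, , ] <- 0.3                       # hit in all lines, all doses
  fold[2, , 1:3] <- 0.3; fold[2, , 4] <- 0.9   # misses the fourth line
  fold[3, 1, ] <- 0.45                     # one dose under 0.5 in all lines
  wells <- manual_screen_table(fold, doses, lines)
  hits <- call_primary_hits(normalize_plates(wells), cell_lines = lines)
  expect_true(hits$primary_hit[hits$compound == "cmpd_001"])
  expect_false(hits$primary_hit[hits$compound == "cmpd_002"])
  expect_true(hits$primary_hit[hits$compound == "cmpd_003"])
  expect_equal(hits$n_lines_with_hit_dose[hits$compound == "cmpd_002"], 3)
})

test_that("a seeded screen with 10 planted hits recovers exactly those 10", {
  planted <- setNames(as.list(rep(0.3, 10)), sprintf("cmpd_%03d", seq(5, 95, 10)))
  spec <- screen_spec(n_compounds = 100, planted_hits = planted)
  sc <- gen_screen(spec, seed = 42)
  norm <- screen_robust_z(normalize_plates(sc$wells))
  hits <- call_primary_hits(norm, cell_lines = spec$cell_lines)
  expect_identical(sort(hits$compound[hits$primary_hit]),
                   sort(names(planted)))
  noms <- nominate_validation_hits(norm)
  expect_identical(sort(noms$compound[noms$nominated]),
                   sort(names(planted)))
})

test_that("per-plate distortions leave fold changes, z-scores and calls alone", {
  planted <- list(cmpd_002 = 0.25, cmpd_007 = c(0.2, 0.3, 0.9))
  spec <- screen_spec(n_compounds = 20, planted_hits = planted)
  base <- gen_screen(spec, seed = 3)$wells
  distorted <- base
  plates <- unique(base$plate_id)
  set.seed(11)
  for (p in plates) {
    distorted$count[distorted$plate_id == p] <-
      distorted$count[distorted$plate_id == p] * runif(1, 0.3, 3)
  }
  n1 <- screen_robust_z(normalize_plates(base))
  n2 <- screen_robust_z(normalize_plates(distorted))
  expect_equal(n1$wells$fold_change, n2$wells$fold_change, tolerance = 1e-12)
  expect_equal(n1$wells$robust_z, n2$wells$robust_z, tolerance = 1e-12)
  h1 <- call_primary_hits(n1); h2 <- call_primary_hits(n2)
  expect_identical(h1$primary_hit, h2$primary_hit)
  expect_equal(h1, h2, tolerance = 1e-12)
  v1 <- nominate_validation_hits(n1); v2 <- nominate_validation_hits(n2)
  expect_identical(v1$nominated, v2$nominated)
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("nomination needs z < -2 at two or more dose points", {
  lines <- sprintf("line_%d", 1:4)
  doses <- c(5, 0.5, 0.05)
  # 30 background compounds near control, two engineered profiles
  n_cmpd <- 32
  fold <- array(1, dim = c(n_cmpd, 3, 4))
  set.seed(2)
  fold[3:n_cmpd, , ] <- fold[3:n_cmpd, , ] * (1 + rnorm((n_cmpd - 2) * 12, 0, 0.05))
  fold[1, 1:2, ] <- 0.3                  # strong at two doses -> nominated
  fold[2, 1, ] <- 0.3                    # strong at one dose -> not nominated
  wells <- manual_screen_table(fold, doses, lines)
  norm <- screen_robust_z(normalize_plates(wells))
  noms <- nominate_validation_hits(norm)
  expect_true(noms$nominated[noms$compound == "cmpd_001"])
  expect_false(noms$nominated[noms$compound == "cmpd_002"])
  expect_equal(noms$n_doses_below_cut[noms$compound == "cmpd_001"], 2)
})

test_that("lowering a nominated compound's counts never un-nominates it", {
  planted <- list(cmpd_004 = 0.3)
  spec <- screen_spec(n_compounds = 20, planted_hits = planted)
  sc <- gen_screen(spec, seed = 6)
  wells <- sc$wells
  noms1 <- nominate_validation_hits(screen_robust_z(normalize_plates(wells)))
  expect_true(noms1$nominated[noms1$compound == "cmpd_004"])
  wells$count[wells$compound %in% "cmpd_004"] <-
    wells$count[wells$compound %in% "cmpd_004"] * 0.5
  noms2 <- nominate_validation_hits(screen_robust_z(normalize_plates(wells)))
  expect_true(noms2$nominated[noms2$compound == "cmpd_004"])
})

test_that("null screens rarely nominate and planted strong hits always do", {
  false_noms <- integer(0)
  planted_found <- logical(0)
  for (seed in 1:25) {
    null_sc <- gen_screen(screen_spec(n_compounds = 100), seed = seed)
    noms <- nominate_validation_hits(
      screen_robust_z(normalize_plates(null_sc$wells)))
    false_noms <- c(false_noms, sum(noms$nominated))

    spec <- screen_spec(n_compounds = 100,
                        planted_hits = list(cmpd_050 = c(0.3, 0.3, 1)))
    sc <- gen_screen(spec, seed = seed + 1000)
    noms2 <- nominate_validation_hits(
      screen_robust_z(normalize_plates(sc$wells)))
    planted_found <- c(planted_found,
                       noms2$nominated[noms2$compound == "cmpd_050"])
  }
  expect_true(all(false_noms <= 2))
  expect_gte(mean(planted_found), 0.95)
})
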