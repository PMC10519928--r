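# Spring-network mechanics: series stiffness, force partition, callus
# stiffness estimation and its algebraic inverse.

test_that("series equivalent stiffness matches the published per-animal values", {
  # kN/mm inputs from the cohort reference; S5 is the known inconsistent row
  expect_equal(series_equivalent_stiffness(309.85, 356.74), 165.82,
               tolerance = 0.01 / 165.82)
  expect_equal(series_equivalent_stiffness(218.43, 236.98), 113.67,
               tolerance = 0.01 / 113.67)
  ref <- ovine_stiffness_reference()
  ok <- ref$id != "S5"
  expect_true(all(abs(ref$kb_series_kn_mm[ok] - ref$kb_kn_mm[ok]) <= 0.01))
  expect_false(ref$kb_consistent[ref$id == "S5"])
})

test_that("series stiffness is symmetric, halves equal springs, and is bounded", {
  ks <- c(10, 123.4, 5e5)
  for (k in ks) expect_equal(series_equivalent_stiffness(k, k), k / 2)
  set.seed(11)
  a <- runif(50, 1, 1e6); b <- runif(50, 1, 1e6)
  expect_equal(series_equivalent_stiffness(a, b),
               series_equivalent_stiffness(b, a))
  expect_true(all(series_equivalent_stiffness(a, b) < pmin(a, b)))
  expect_error(series_equivalent_stiffness(-1, 10), "k_bp")
  expect_error(series_equivalent_stiffness(10, 0), "k_bd")
})

test_that("rod stiffness from an area profile follows the series-slice sum", {
  # uniform rod: E * A / L, evaluated by hand
  expect_equal(cortical_stiffness_from_profile(rep(144.79, 30), 1, 21000),
               21000 * 144.79 / 30, tolerance = 1e-12)
  expect_equal(cortical_stiffness_from_profile(144.79, 0.3), 21000 * 144.79 / 0.3)
  # two equal slices halve the single-slice stiffness
  expect_equal(cortical_stiffness_from_profile(c(100, 100), 0.5),
               cortical_stiffness_from_profile(100, 0.5) / 2)
  # independent oracle: explicit series sum over a varying profile
  areas <- c(120, 150, 180, 140)
  oracle <- 1 / sum(0.3 / (21000 * areas))
  expect_equal(cortical_stiffness_from_profile(areas, 0.3), oracle)
  expect_error(cortical_stiffness_from_profile(c(100, -5, 80), 0.3), "slice index 2")
})

test_that("callus force conserves the internal force", {
  expect_identical(callus_force(100, 90), 10)
  expect_identical(callus_force(250, 25), 225)
  expect_identical(callus_force(77.7, 77.7), 0)
  f_i <- runif(20, 0, 300); f_f <- runif(20, 0, 300)
  expect_identical(callus_force(f_i, f_f) + f_f, f_i)
})

test_that("callus stiffness matches the printed partition formula and limits", {
  k_f <- 593; k_b <- 113670
  # equal forces: hand-evaluated K_f*K_b/(K_b+K_f), any magnitude
  expect_equal(callus_stiffness(50, 50, k_f, k_b), k_f * k_b / (k_b + k_f))
  expect_equal(callus_stiffness(212.3, 212.3, k_f, k_b), k_f * k_b / (k_b + k_f))
  # algebraic limit of the printed formula: K_c -> K_b as F_f -> 0+
  expect_equal(callus_stiffness(1e-9 * 100, 100, k_f, k_b), k_b,
               tolerance = 1e-5)
  # invalid stances yield NA, not numbers
  expect_true(is.na(callus_stiffness(0, 10, k_f, k_b)))
  expect_true(is.na(callus_stiffness(10, -1, k_f, k_b)))
  expect_error(callus_stiffness(1, 1, -5, k_b), "k_f")
})

test_that("forward partition inverts the stiffness estimator exactly", {
  k_f <- 593; k_b <- 113670
  # no callus path: fixator carries everything
  p0 <- forward_load_partition(250, 0, k_f, k_b)
  expect_identical(p0$f_f, 250); expect_identical(p0$f_c, 0)
  # crossover stiffness splits the load in half (solved analytically)
  k_half <- k_f * k_b / (k_b + k_f)
  ph <- forward_load_partition(200, k_half, k_f, k_b)
  expect_equal(ph$f_f, 100); expect_equal(ph$f_c, 100)
  # round trip over random valid draws
  set.seed(7)
  n <- 1000
  k_fr <- runif(n, 100, 2000); k_br <- runif(n, 1e4, 5e5)
  k_cr <- runif(n, 1e-3, 0.99) * k_br
  f_ir <- runif(n, 1, 500)
  p <- forward_load_partition(f_ir, k_cr, k_fr, k_br)
  expect_equal(p$f_f + p$f_c, f_ir, tolerance = 1e-12)
  back <- callus_stiffness(p$f_f, p$f_c, k_fr, k_br)
  expect_equal(back, k_cr, tolerance = 1e-9)
  expect_error(forward_load_partition(100, k_b, k_f, k_b), "below")
})

test_that("load share is monotone decreasing in callus stiffness", {
  k_f <- 593; k_b <- 113670
  kc <- seq(0, k_b * 0.999, length.out = 400)
  p <- forward_load_partition(rep(100, length(kc)), kc, k_f, k_b)
  lam <- load_share_fraction(p$f_f, rep(100, length(kc)))
  expect_equal(lam[1], 1)
  expect_true(all(diff(lam) < 0))
  expect_equal(load_share_fraction(90, 100), 0.9)
  expect_equal(load_share_fraction(0, 100), 0)
  expect_error(load_share_fraction(10, 0), "f_i")
})

test_that("force-ratio calibration averages in-window peak pairs", {
  peaks <- data.frame(day = c(8, 10), grf = c(200, 220), ff = c(100, 110))
  cal <- calibrate_force_ratio(peaks)
  expect_equal(cal$r, 0.5)
  expect_equal(cal$n_samples, 2L)
  expect_equal(calibrate_force_ratio(
    data.frame(day = 9, grf = 300, ff = 90))$r, 0.3)
  # out-of-window treads are ignored (half-open window: day 14 excluded)
  peaks2 <- rbind(peaks, data.frame(day = c(14, 20), grf = c(100, 100),
                                    ff = c(1, 1)))
  expect_equal(calibrate_force_ratio(peaks2)$r, 0.5)
  expect_error(calibrate_force_ratio(peaks, window = c(20, 25)), "window")
  expect_warning(
    cal3 <- calibrate_force_ratio(
      data.frame(day = c(8, 8), grf = c(0, 200), ff = c(5, 100))),
    "skipped")
  expect_equal(cal3$r, 0.5)
})

test_that("noisy ratio calibration recovers the generating ratio", {
  # oracle: regenerate the same draws and average by brute force
  r_true <- 0.6
  set.seed(99)
  grf <- 250 * rnorm(8, 1, 0.05)
  ff <- r_true * 250 * rnorm(8, 1, 0.05)
  cal <- calibrate_force_ratio(data.frame(day = 8, grf = grf, ff = ff))
  expect_equal(cal$r, mean(ff / grf))
  expect_lt(abs(cal$r - r_true) / r_true, 0.05)
})

test_that("stiffness estimation censors an unloaded fixator", {
  k_f <- 593; k_b <- 113670
  est <- estimate_callus_stiffness(f_f = c(50, 1, 0.5, -2),
                                   f_i = c(100, 100, 100, 100),
                                   k_f, k_b, censor_frac = 0.02)
  expect_false(est$censored[1]); expect_true(est$valid[1])
  expect_true(all(est$censored[2:4]))
  expect_true(all(is.na(est$k_c[2:4])))
  # threshold is configurable
  est2 <- estimate_callus_stiffness(1, 100, k_f, k_b, censor_frac = 0)
  expect_true(est2$valid)
})
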