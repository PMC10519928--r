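# Phantom calibration, segmentation, CSA/TV/BMD profiles, normalization.

test_that("two exact phantoms define the calibration line", {
  dens <- array(0, dim = c(20, 6, 4))
  vol <- make_tiny_volume(dens, spacing = c(1, 1, 1))
  cal <- calibrate_hu_to_bmd(vol)
  expect_equal(cal$slope, 0.001, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1)
})

test_that("noiseless collinear phantoms reproduce the line to 1e-12", {
  # six inserts on density = 0.05 + 0.0012 * HU
  dens6 <- c(0, 0.1, 0.2, 0.4, 0.6, 0.8)
  phantoms <- lapply(seq_along(dens6), function(i)
    phantom_cylinder(paste0("P", i), dens6[i], c(3 + 6 * (i - 1), 3), 1.2))
  hu <- array(0, dim = c(36, 6, 3))
  vol <- voxel_volume(hu, c(1, 1, 1), phantoms = phantoms)
  for (p in phantoms)
    vol$hu[phantom_mask(vol, p)] <- (p$density - 0.05) / 0.0012
  cal <- calibrate_hu_to_bmd(vol)
  expect_equal(cal$slope, 0.0012, tolerance = 1e-12)
  expect_equal(cal$intercept, 0.05, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
})

test_that("noisy phantom calibration matches the normal-equation oracle", {
  dens6 <- c(0, 0.1, 0.2, 0.4, 0.6, 0.8)
  phantoms <- lapply(seq_along(dens6), function(i)
    phantom_cylinder(paste0("P", i), dens6[i], c(3 + 6 * (i - 1), 3), 1.2))
  hu <- array(0, dim = c(36, 6, 3))
  vol <- voxel_volume(hu, c(1, 1, 1), phantoms = phantoms)
  set.seed(21)
  for (p in phantoms) {
    m <- phantom_mask(vol, p)
    vol$hu[m] <- p$density / 0.001 + rnorm(sum(m), 0, 2)
  }
  cal <- calibrate_hu_to_bmd(vol)
  # brute-force normal equations on the per-region mean HU
  mu <- vapply(phantoms, function(p) mean(vol$hu[phantom_mask(vol, p)]),
               numeric(1))
  X <- cbind(1, mu)
  beta <- solve(crossprod(X), crossprod(X, dens6))
  expect_equal(cal$intercept, beta[1], tolerance = 1e-10)
  expect_equal(cal$slope, beta[2], tolerance = 1e-10)
  expect_lt(abs(cal$slope - 0.001) / 0.001, 0.02)
})

test_that("degenerate phantom designs raise calibration errors", {
  dens <- array(0, dim = c(20, 6, 3))
  vol <- make_tiny_volume(dens)
  vol$phantoms <- vol$phantoms[1]
  expect_error(calibrate_hu_to_bmd(vol), "at least two")
  vol2 <- make_tiny_volume(dens)
  vol2$phantoms[[2]]$density <- 0
  expect_error(calibrate_hu_to_bmd(vol2), "distinct")
  vol3 <- make_tiny_volume(dens)
  vol3$hu[] <- 100 # identical mean HU in both inserts
  expect_error(calibrate_hu_to_bmd(vol3), "identical mean HU")
})

test_that("segmentation thresholds mapped density inside the ROI", {
  dens <- array(1.25, dim = c(12, 12, 5))
  vol <- make_tiny_volume(dens, defect_span = c(1, 4))
  cal <- perfect_calibration()
  mask <- segment_mineralized(vol, cal)
  roi <- roi_mask(vol)
  expect_true(all(mask[roi])) # full ROI at density 1.25
  expect_false(any(mask[!roi])) # phantoms excluded
  vol0 <- make_tiny_volume(array(0, dim = c(12, 12, 5)))
  m0 <- segment_mineralized(vol0, cal)
  expect_false(any(m0[roi_mask(vol0)]))
})

test_that("raising the threshold never grows any slice (mask monotonicity)", {
  set.seed(31)
  dens <- array(runif(10 * 10 * 6, 0, 1.3), dim = c(10, 10, 6))
  vol <- make_tiny_volume(dens)
  cal <- perfect_calibration()
  prev <- csa_profile(segment_mineralized(vol, cal, 0.05))$csa_mm2
  for (thr in c(0.15, 0.4, 0.8, 1.2)) {
    cur <- csa_profile(segment_mineralized(vol, cal, thr))$csa_mm2
    expect_true(all(cur <= prev + 1e-12))
    prev <- cur
  }
})

test_that("CSA of a digital cylinder matches the analytic area", {
  vol <- make_cylinder_volume(radius = 6.789, spacing = 0.3, extent_xy = 18,
                              length_z = 6)
  mask <- segment_mineralized(vol, perfect_calibration())
  prof <- csa_profile(mask)
  analytic <- pi * 6.789^2 # 144.79 mm^2
  expect_true(all(abs(prof$csa_mm2 - analytic) / analytic < 0.02))
  # voxel-count oracle: the profile is exactly count * pixel area
  counts <- apply(mask, 3, sum)
  expect_equal(prof$csa_mm2, counts * 0.3^2)
  # empty slices report 0
  vol$hu[, , 1] <- 0
  prof0 <- csa_profile(segment_mineralized(vol, perfect_calibration()))
  expect_equal(prof0$csa_mm2[1], 0)
})

test_that("halving the voxel spacing tightens the CSA error", {
  err <- vapply(c(0.8, 0.4, 0.2), function(sp) {
    vol <- make_cylinder_volume(radius = 5.2, spacing = sp, extent_xy = 16,
                                length_z = 4 * sp)
    prof <- csa_profile(segment_mineralized(vol, perfect_calibration()))
    abs(mean(prof$csa_mm2) - pi * 5.2^2) / (pi * 5.2^2)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("a step in radius appears as a step in the CSA profile", {
  v1 <- make_cylinder_volume(radius = 6, spacing = 0.5, extent_xy = 20,
                             length_z = 5)
  v2 <- make_cylinder_volume(radius = 3, spacing = 0.5, extent_xy = 20,
                             length_z = 5)
  stacked <- voxel_volume(array(c(v1$hu, v2$hu), dim = c(40, 40, 20)),
                          spacing = rep(0.5, 3), phantoms = v1$phantoms)
  prof <- csa_profile(segment_mineralized(stacked, perfect_calibration()))
  expect_true(all(abs(prof$csa_mm2[1:10] - pi * 36) / (pi * 36) < 0.05))
  expect_true(all(abs(prof$csa_mm2[11:20] - pi * 9) / (pi * 9) < 0.08))
})

test_that("total volume integrates CSA over the defect plus margins", {
  prof <- data.frame(z_mm = seq(0.5, 49.5, by = 1), csa_mm2 = 120)
  # uniform 120 mm^2 over a 35 mm window -> 4.2 cm^3 by the rectangle rule
  expect_equal(total_volume(prof, defect_span = c(17.5, 32.5), margin = 10),
               35 * 120 / 1000)
  expect_equal(total_volume(prof, c(17.5, 32.5), margin = 0), 15 * 120 / 1000)
  # empty mask integrates to zero
  prof0 <- data.frame(z_mm = prof$z_mm, csa_mm2 = 0)
  expect_equal(total_volume(prof0, c(17.5, 32.5)), 0)
  expect_warning(total_volume(prof, c(5, 45), margin = 10), "clipped")
})

test_that("TV is additive over adjacent windows", {
  set.seed(8)
  prof <- data.frame(z_mm = seq(0.25, 39.75, by = 0.5),
                     csa_mm2 = runif(80, 50, 300))
  tv_ab <- total_volume(prof, c(5, 20), margin = 0)
  tv_bc <- total_volume(prof, c(20, 35), margin = 0)
  tv_ac <- total_volume(prof, c(5, 35), margin = 0)
  expect_equal(tv_ab + tv_bc, tv_ac, tolerance = 1e-12)
})

test_that("BMD profile averages masked voxels and reports empty slices as NA", {
  dens <- array(0, dim = c(10, 8, 4))
  dens[3:6, 3:6, ] <- 1.25
  dens[, , 4] <- 0 # empty slice
  vol <- make_tiny_volume(dens, defect_span = c(0, 3))
  cal <- perfect_calibration()
  mask <- segment_mineralized(vol, cal)
  bp <- bmd_profile(vol, mask, cal)
  expect_equal(bp$profile$bmd_g_cm3[1:3], rep(1.25, 3))
  expect_true(is.na(bp$profile$bmd_g_cm3[4]))
  expect_equal(bp$summary_g_cm3, 1.25)
  # two equal-size regions at 0.5 and 1.0 average to 0.75
  dens2 <- array(0, dim = c(10, 8, 2))
  dens2[3:4, 3:6, ] <- 0.5
  dens2[5:6, 3:6, ] <- 1.0
  vol2 <- make_tiny_volume(dens2, defect_span = c(0, 2), with_phantoms = FALSE)
  m2 <- segment_mineralized(vol2, cal)
  bp2 <- bmd_profile(vol2, m2, cal)
  expect_equal(bp2$profile$bmd_g_cm3, rep(0.75, 2))
  # fully empty mask over the span warns and yields NA
  vol3 <- make_tiny_volume(array(0, dim = c(10, 8, 2)), defect_span = c(0, 2))
  m3 <- segment_mineralized(vol3, cal)
  expect_warning(bp3 <- bmd_profile(vol3, m3, cal), "empty")
  expect_true(is.na(bp3$summary_g_cm3))
})

test_that("generator-designed callus density is recovered by averaging", {
  set.seed(17)
  dens <- array(rnorm(20 * 20 * 8, 0.79, 0.05), dim = c(20, 20, 8))
  vol <- make_tiny_volume(dens, defect_span = c(0, 8))
  # oracle: direct average of the generated voxels above threshold
  cal <- perfect_calibration()
  mask <- segment_mineralized(vol, cal)
  bp <- bmd_profile(vol, mask, cal)
  roi <- roi_mask(vol)
  oracle <- mean(dens[roi & dens >= 0.15])
  expect_equal(bp$summary_g_cm3, oracle, tolerance = 1e-10)
  expect_lt(abs(bp$summary_g_cm3 - 0.79) / 0.79, 0.02)
})

test_that("contralateral normalization returns matched percentages", {
  treated <- list(tv_cm3 = 4.34, csa_mm2 = 289.58, bmd_g_cm3 = 1.25)
  control <- list(tv_cm3 = 2.17, csa_mm2 = 144.79, bmd_g_cm3 = 1.25)
  pct <- normalize_to_contralateral(treated, control)
  expect_equal(pct$tv_pct, 200)
  expect_equal(pct$csa_pct, 200, tolerance = 1e-12)
  expect_equal(pct$bmd_pct, 100)
  ident <- normalize_to_contralateral(control, control)
  expect_equal(unlist(ident), c(tv_pct = 100, csa_pct = 100, bmd_pct = 100))
  bad <- control; bad$bmd_g_cm3 <- 0
  expect_error(normalize_to_contralateral(treated, bad), "zero or missing")
})

test_that("volumes round-trip through NIfTI plus sidecar", {
  dens <- array(runif(8 * 8 * 5, 0, 1), dim = c(8, 8, 5))
  vol <- make_tiny_volume(dens, spacing = c(0.5, 0.5, 0.5),
                          defect_span = c(0.5, 2))
  path <- tempfile(fileext = ".nii.gz")
  write_ct_volume(vol, path, extra = list(truth = list(bmd_g_cm3 = 0.79)))
  back <- read_ct_volume(path)
  expect_equal(back$volume$hu, vol$hu, tolerance = 1e-6)
  expect_equal(back$volume$spacing, vol$spacing)
  expect_equal(back$volume$defect_span, vol$defect_span)
  expect_equal(length(back$volume$phantoms), 2L)
  expect_equal(back$sidecar$truth$bmd_g_cm3, 0.79)
  unlink(c(path, sub("\\.nii\\.gz$", ".json", path)))
})
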