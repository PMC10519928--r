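# In-code fixtures shared across test files.

# half-sine stance train in the trace dialect
make_trace <- function(day = 10, amplitudes = rep(250, 8), ff_fraction = 0.9,
                       fs = 100, stance_s = 0.5, gap_s = 0.4) {
  n_st <- round(stance_s * fs) + 1
  n_gap <- round(gap_s * fs)
  shape <- sin(pi * seq(0, 1, length.out = n_st))
  gap <- rep(0, n_gap)
  grf <- unlist(lapply(amplitudes, function(a) c(gap, a * shape, gap)))
  data.frame(day = day, tread_id = rep(seq_along(amplitudes),
                                       each = n_st + 2 * n_gap),
             t = seq_along(grf) / fs, grf_N = grf, ff_N = ff_fraction * grf)
}

# tiny calibrated volume: density grid -> HU via a known line (slope 0.001),
# with two phantom inserts so calibrate_hu_to_bmd() can run
make_tiny_volume <- function(density, spacing = c(1, 1, 1), defect_span = NULL,
                             slope = 0.001, intercept = 0,
                             with_phantoms = TRUE) {
  dims <- dim(density)
  phantoms <- if (with_phantoms) list(
    phantom_cylinder("lo", 0.0, c(1.0, 1.0), 0.9),
    phantom_cylinder("hi", 0.8, c(dims[1] * spacing[1] - 1.0, 1.0), 0.9))
  else list()
  hu <- (density - intercept) / slope
  # stamp the phantom densities into the grid
  vol <- voxel_volume(hu, spacing, defect_span = defect_span,
                      phantoms = phantoms)
  for (p in phantoms) vol$hu[phantom_mask(vol, p)] <- (p$density - intercept) / slope
  vol
}

# digital solid cylinder of given radius along z, density inside, 0 outside
make_cylinder_volume <- function(radius, extent_xy = 24, length_z = 20,
                                 spacing = 0.5, density = 1.0,
                                 defect_span = NULL) {
  n_xy <- round(extent_xy / spacing)
  n_z <- round(length_z / spacing)
  xs <- (seq_len(n_xy) - 0.5) * spacing - extent_xy / 2
  inside <- outer(xs^2, xs^2, "+") <= radius^2
  dens <- array(rep(as.numeric(inside) * density, n_z),
                dim = c(n_xy, n_xy, n_z))
  make_tiny_volume(dens, spacing = rep(spacing, 3), defect_span = defect_span)
}

perfect_calibration <- function() {
  structure(list(slope = 0.001, intercept = 0, r_squared = 1, n_regions = 2),
            class = "calibration_line")
}
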