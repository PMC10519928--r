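# Forward simulator: synthetic healing cohorts with known ground truth.
#
# Each animal carries anchor-based trajectories for apparent callus
# stiffness, GRF recovery (% of healthy), callus mineral density, and callus
# cross-sectional area (% of contralateral). Gait traces are produced by
# pushing the internal force through the exact inverse of the callus
# stiffness estimator, so the analysis pipeline can be scored against the
# generator's truth at every stage.

# deterministic sub-stream seeds below 2^31
mix_seed <- function(a, b) {
  as.integer((abs(a) * 69069 + abs(b) * 1234567 + 97) %% 2147483629)
}

#' Monotone shape-preserving trajectory through anchors
#'
#' Fritsch-Carlson monotone Hermite interpolation through `(day, value)`
#' anchors: passes through every anchor exactly, introduces no overshoot
#' between monotone anchors, and holds the end values outside the anchored
#' range.
#'
#' @param anchors Data frame with columns `day` (distinct) and `value`.
#' @param t Days at which to evaluate.
#' @return Values at `t`.
#' @export
trajectory <- function(anchors, t) {
  stopifnot(is.data.frame(anchors), all(c("day", "value") %in% names(anchors)))
  if (nrow(anchors) < 2L) stop("need at least two anchors")
  if (anyDuplicated(anchors$day)) stop("duplicate anchor days")
  o <- order(anchors$day)
  d <- anchors$day[o]; v <- anchors$value[o]
  f <- stats::splinefun(d, v, method = "monoH.FC")
  f(pmin(pmax(t, d[1]), d[length(d)]))
}

#' Default synthetic healing cohort
#'
#' Builds `n` animal ground truths mirroring the monitored ovine
#' critical-size metatarsal defect study: body weight 60 kg, fixator
#' stiffness 593 N/mm, fragment stiffnesses recycled from the per-animal
#' reference table ([ovine_stiffness_reference()]), and anchor schedules
#' for the monitored quantities:
#' \itemize{
#'   \item callus stiffness: 0 N/mm through the 13-day latency (no
#'     mineralized bridge, so the early calibration `F_i ~ F_f` holds),
#'     60 N/mm at day 14, the crossover stiffness `K_f K_b / (K_b + K_f)`
#'     at day 30, 650 N/mm at day 40, 7 kN/mm at day 60, 15 kN/mm at day 70,
#'     and a late consolidation anchor of `min(50 kN/mm, 0.8 K_b)` at day
#'     180 so the fixator force settles toward zero after recovery;
#'   \item GRF: 42% of healthy at day 7, 70.5% at day 120, 93% at day 180;
#'   \item BMD: 0.45 g HA/cm^3 at day 0 (scaffold mineral), 0.79 at day 65,
#'     0.81 at day 123, 1.1875 at day 365 (95% of the 1.25 contralateral);
#'   \item CSA: 100% of contralateral at day 0, 229.49% at day 200,
#'     156.13% at day 365.
#' }
#' Contralateral references: CSA 144.79 mm^2, TV 2.17 cm^3 (15 mm span),
#' BMD 1.25 g HA/cm^3.
#'
#' @param n Number of animals (>= 1). Default 8.
#' @param seed Base seed; every derived stream is a deterministic function
#'   of it. Default 42.
#' @param body_weight Body weight (kg). Default 60.
#' @param k_f Fixator stiffness (N/mm). Default 593.
#' @param r_true True internal-force to GRF ratio the pipeline must recover.
#'   Default 1.0.
#' @param jitter Per-animal multiplicative anchor jitter (lognormal sd on
#'   the anchor values of each trajectory). Default 0.
#' @param sigma_force Multiplicative Gaussian sd on sensed force peaks.
#'   Default 0.05.
#' @param sigma_hu Additive HU noise sd. Default 2.
#' @param sigma_bmd Within-callus density heterogeneity sd (g HA/cm^3).
#'   Default 0.05.
#' @return List of `animal_truth` objects (class `healing_cohort`).
#' @export
default_cohort <- function(n = 8, seed = 42, body_weight = 60, k_f = 593,
                           r_true = 1.0, jitter = 0, sigma_force = 0.05,
                           sigma_hu = 2, sigma_bmd = 0.05) {
  if (n < 1) stop("'n' must be >= 1")
  ref <- ovine_stiffness_reference()
  set.seed(mix_seed(seed, 1))
  cohort <- lapply(seq_len(n), function(i) {
    row <- ref[((i - 1L) %% nrow(ref)) + 1L, ]
    k_bp <- row$kbp_kn_mm * 1000
    k_bd <- row$kbd_kn_mm * 1000
    k_b <- series_equivalent_stiffness(k_bp, k_bd)
    k_cross <- k_f * k_b / (k_b + k_f)
    jfac <- function() if (jitter > 0) exp(stats::rnorm(1, 0, jitter)) else 1
    # late consolidation anchor: stiffening continues past day 70 so the
    # fixator force settles toward zero; capped below K_b (model validity)
    kc_late <- min(50000, 0.8 * k_b)
    kc <- data.frame(day = c(0, 13, 14, 30, 40, 60, 70, 180),
                     value = c(0, 0, 60 * jfac(), k_cross, 650 * jfac(),
                               7000 * jfac(), 15000 * jfac(), kc_late))
    kc$value <- cummax(kc$value) # jitter must not break monotone growth
    grf <- data.frame(day = c(7, 120, 180), value = c(42, 70.5, 93) * jfac())
    bmd <- data.frame(day = c(0, 65, 123, 365),
                      value = c(0.45, 0.79, 0.81, 1.1875) * jfac())
    csa <- data.frame(day = c(0, 200, 365),
                      value = c(100, 229.49, 156.13) * jfac())
    structure(list(
      id = sprintf("A%02d", i), body_weight = body_weight, k_f = k_f,
      k_bp = k_bp, k_bd = k_bd, k_b = k_b, r_true = r_true,
      kc_anchors = kc, grf_anchors = grf, bmd_anchors = bmd,
      csa_pct_anchors = csa,
      sigma_force = sigma_force, sigma_hu = sigma_hu, sigma_bmd = sigma_bmd,
      sacrifice_day = row$sacrifice_day, ct_days = row$ct_days[[1]],
      contralateral = list(csa_mm2 = 144.79, tv_cm3 = 2.17,
                           bmd_g_cm3 = 1.25, outer_radius_mm = 8.4),
      seed = mix_seed(seed, 1000 + i)), class = "animal_truth")
  })
  structure(cohort, class = "healing_cohort")
}

#' @export
print.animal_truth <- function(x, ...) {
  cat(sprintf("Animal %s: BW %g kg, K_f %g N/mm, K_b %.0f N/mm, sacrifice day %g\n",
              x$id, x$body_weight, x$k_f, x$k_b, x$sacrifice_day))
  invisible(x)
}

#' @export
print.healing_cohort <- function(x, ...) {
  cat("Synthetic healing cohort of", length(x), "animal(s)\n")
  invisible(x)
}

#' Designed (noise-free) state of an animal on a given day
#'
#' Evaluates the ground-truth trajectories and the forward load partition:
#' peak GRF, internal/fixator/callus forces, callus stiffness, fixator
#' load-share fraction, BMD and CSA%.
#'
#' @param truth An `animal_truth`.
#' @param day Days post-surgery (vectorized).
#' @return Data frame, one row per day.
#' @export
design_state <- function(truth, day) {
  grf <- trajectory(truth$grf_anchors, day) / 100 *
    healthy_grf(truth$body_weight)
  k_c <- trajectory(truth$kc_anchors, day)
  f_i <- truth$r_true * grf
  part <- forward_load_partition(f_i, k_c, truth$k_f, truth$k_b)
  data.frame(day = day, grf_N = grf, f_i = f_i, f_f = part$f_f,
             f_c = part$f_c, k_c = k_c,
             load_share = ifelse(f_i > 0, part$f_f / f_i, NA_real_),
             grf_pct = trajectory(truth$grf_anchors, day),
             bmd_g_cm3 = trajectory(truth$bmd_anchors, day),
             csa_pct = trajectory(truth$csa_pct_anchors, day))
}

#' Designed crossover and stabilization days
#'
#' `design_crossover_day` solves `K_c(t) = K_f K_b / (K_b + K_f)` (the
#' stiffness at which fixator and callus carry equal load);
#' `design_stabilization_day` solves for the load-share fraction reaching
#' `band_frac`.
#'
#' @param truth An `animal_truth`.
#' @return Day (numeric).
#' @export
design_crossover_day <- function(truth) {
  k_cross <- truth$k_f * truth$k_b / (truth$k_b + truth$k_f)
  f <- function(t) trajectory(truth$kc_anchors, t) - k_cross
  rng <- range(truth$kc_anchors$day)
  stats::uniroot(f, lower = rng[1], upper = rng[2], tol = 1e-8)$root
}

#' @rdname design_crossover_day
#' @param band_frac Load-share fraction defining stabilization. Default 0.05.
#' @export
design_stabilization_day <- function(truth, band_frac = 0.05) {
  f <- function(t) {
    k_c <- trajectory(truth$kc_anchors, t)
    part <- forward_load_partition(1, k_c, truth$k_f, truth$k_b)
    part$f_f - band_frac
  }
  rng <- range(truth$kc_anchors$day)
  stats::uniroot(f, lower = rng[1], upper = rng[2], tol = 1e-8)$root
}

#' Simulate one day of instrumented gait
#'
#' Generates a walking-platform/fixator trace of `n_treads` half-sine
#' stance pulses. The designed peak GRF follows the animal's recovery
#' trajectory; the fixator channel carries
#' `F_f = lambda(K_c(day)) * r_true * GRF`. Each tread's sensed peak gets an
#' independent multiplicative Gaussian error per channel (platform and load
#' cells are separate instruments).
#'
#' @param truth An `animal_truth`.
#' @param day Days post-surgery (>= 0).
#' @param n_treads Number of stance events. Default 8.
#' @param fs Sampling rate (Hz). Default 100.
#' @param stance_s Stance duration (s). Default 0.5.
#' @param gap_s Inter-stance gap (s). Default 0.4.
#' @param sigma Multiplicative peak noise sd; defaults to the animal's.
#' @return Trace data frame: `day`, `tread_id`, `t`, `grf_N`, `ff_N`.
#' @export
simulate_gait_day <- function(truth, day, n_treads = 8, fs = 100,
                              stance_s = 0.5, gap_s = 0.4,
                              sigma = truth$sigma_force) {
  if (day < 0) stop("'day' must be non-negative")
  if (n_treads < 1) stop("'n_treads' must be >= 1")
  st <- design_state(truth, day)
  set.seed(mix_seed(truth$seed, 100 * day + 3))
  n_st <- round(stance_s * fs)
  if (n_st %% 2L == 0L) n_st <- n_st + 1L # odd length: the pulse attains its peak exactly
  n_gap <- round(gap_s * fs)
  shape <- sin(pi * seq(0, 1, length.out = n_st))
  pergap <- rep(0, n_gap)
  lambda <- if (st$f_i > 0) st$f_f / st$f_i else 1
  out <- vector("list", n_treads)
  t0 <- 0
  for (j in seq_len(n_treads)) {
    ng <- if (sigma > 0) stats::rnorm(1, 1, sigma) else 1
    nf <- if (sigma > 0) stats::rnorm(1, 1, sigma) else 1
    grf <- c(pergap, st$grf_N * ng * shape, pergap)
    ff <- c(pergap, st$f_f * nf * shape, pergap)
    tt <- t0 + seq_along(grf) / fs
    out[[j]] <- data.frame(day = day, tread_id = j, t = tt,
                           grf_N = grf, ff_N = ff)
    t0 <- tt[length(tt)]
  }
  do.call(rbind, out)
}

#' Simulate a multi-day gait series
#' @param truth An `animal_truth`.
#' @param days Monitoring days.
#' @param ... Passed to [simulate_gait_day()].
#' @return Long trace data frame over all days.
#' @export
simulate_gait_series <- function(truth, days, ...) {
  do.call(rbind, lapply(days, function(d) simulate_gait_day(truth, d, ...)))
}

#' Default gait monitoring schedule (days post-surgery)
#'
#' Two to three sessions per week from the end of the latency week through
#' the consolidation phase, weekly until month six, then biweekly check-ups
#' through the remodeling year.
#' @export
default_monitoring_schedule <- function() {
  c(seq(7, 13, by = 2), seq(14, 70, by = 2), seq(77, 180, by = 7),
    seq(194, 365, by = 14))
}

# internal geometry: digital metatarsus + phantom battery
ct_geometry <- function(spacing, extent = c(40, 56, 50)) {
  n <- round(extent / spacing)
  list(n = n, extent = n * spacing,
       bone_center = c(20, 20),
       phantom_y = 47, phantom_x = seq(5, 35, by = 6), phantom_r = 2.5,
       defect_span = c(17.5, 32.5))
}

#' Simulate a CT-like volume of the operated (or contralateral) limb
#'
#' Digital metatarsus along z: a cortical annulus (mineral density
#' 1.25 g HA/cm^3, cross-section matching the contralateral reference
#' 144.79 mm^2) interrupted by the 15 mm defect span, which carries a solid
#' callus cylinder whose area follows the CSA% trajectory and whose voxel
#' densities are Gaussian around the BMD trajectory. Six phantom cylinders
#' of known density (0 to 0.8 g HA/cm^3) run alongside. Densities map to HU
#' through a configured true line (`HU = (density - intercept) / slope`)
#' plus additive HU noise. The contralateral limb is the uninterrupted
#' annulus.
#'
#' @param truth An `animal_truth`.
#' @param day Days post-surgery (sets BMD and CSA for the treated limb).
#' @param limb `"treated"` or `"contralateral"`.
#' @param spacing Isotropic voxel spacing (mm). Default 0.3.
#' @param sigma_hu,sigma_bmd Noise overrides; defaults from `truth`. Set
#'   both to 0 for a noiseless volume.
#' @param slope_true,intercept_true True HU-to-density line. Defaults 0.001
#'   g HA/cm^3 per HU and 0.
#' @param phantom_densities Insert densities. Default
#'   `c(0, 0.1, 0.2, 0.4, 0.6, 0.8)`.
#' @return List with `volume` (a `voxel_volume`) and `truth` (designed
#'   values: `csa_mm2`, `tv_cm3`, `bmd_g_cm3`, the true calibration line,
#'   `day`, `limb`).
#' @export
simulate_ct_volume <- function(truth, day, limb = c("treated", "contralateral"),
                               spacing = 0.3, sigma_hu = truth$sigma_hu,
                               sigma_bmd = truth$sigma_bmd,
                               slope_true = 0.001, intercept_true = 0,
                               phantom_densities = c(0, 0.1, 0.2, 0.4, 0.6, 0.8)) {
  limb <- match.arg(limb)
  if (spacing <= 0) stop("'spacing' must be positive")
  if (day < 0) stop("'day' must be non-negative")
  geom <- ct_geometry(spacing)
  n <- geom$n
  set.seed(mix_seed(truth$seed, 7e5 + 100 * day + (limb == "contralateral")))

  xs <- (seq_len(n[1]) - 0.5) * spacing
  ys <- (seq_len(n[2]) - 0.5) * spacing
  zs <- (seq_len(n[3]) - 0.5) * spacing
  d2 <- outer((xs - geom$bone_center[1])^2, (ys - geom$bone_center[2])^2, "+")

  cort <- truth$contralateral
  r_out <- cort$outer_radius_mm
  r_in <- sqrt(r_out^2 - cort$csa_mm2 / pi)
  annulus <- which(d2 <= r_out^2 & d2 > r_in^2)

  csa_pct <- trajectory(truth$csa_pct_anchors, day)
  callus_area <- csa_pct / 100 * cort$csa_mm2
  r_callus <- sqrt(callus_area / pi)
  callus <- which(d2 <= r_callus^2)
  bmd_day <- trajectory(truth$bmd_anchors, day)

  zin <- in_span(zs, geom$defect_span)
  dens <- matrix(0, n[1] * n[2], n[3])
  if (limb == "treated") {
    dens[annulus, !zin] <- cort$bmd_g_cm3
    ncal <- length(callus) * sum(zin)
    dens[callus, zin] <- bmd_day +
      if (sigma_bmd > 0) stats::rnorm(ncal, 0, sigma_bmd) else 0
  } else {
    dens[annulus, ] <- cort$bmd_g_cm3
  }
  phantoms <- vector("list", length(phantom_densities))
  for (i in seq_along(phantom_densities)) {
    ctr <- c(geom$phantom_x[i], geom$phantom_y)
    disc <- which(outer((xs - ctr[1])^2, (ys - ctr[2])^2, "+") <= geom$phantom_r^2)
    dens[disc, ] <- phantom_densities[i]
    phantoms[[i]] <- phantom_cylinder(paste0("P", i), phantom_densities[i],
                                      ctr, geom$phantom_r)
  }
  hu <- (dens - intercept_true) / slope_true
  if (sigma_hu > 0) hu <- hu + stats::rnorm(length(hu), 0, sigma_hu)
  dim(hu) <- n

  vol <- voxel_volume(hu, spacing = rep(spacing, 3),
                      defect_span = geom$defect_span, phantoms = phantoms)
  span_mm <- diff(geom$defect_span)
  truth_out <- if (limb == "treated") {
    list(day = day, limb = limb,
         csa_mm2 = callus_area,
         tv_cm3 = (span_mm * callus_area + 2 * 10 * cort$csa_mm2) / 1000,
         bmd_g_cm3 = bmd_day,
         slope_true = slope_true, intercept_true = intercept_true)
  } else {
    list(day = day, limb = limb,
         csa_mm2 = cort$csa_mm2,
         tv_cm3 = span_mm * cort$csa_mm2 / 1000,
         bmd_g_cm3 = cort$bmd_g_cm3,
         slope_true = slope_true, intercept_true = intercept_true)
  }
  list(volume = vol, truth = truth_out)
}

#' Write a full synthetic dataset to disk
#'
#' Produces, per animal: the gait trace CSV (trace dialect), the designed
#' daily truth CSV, treated CT volumes at the animal's CT time-points and
#' one contralateral volume (NIfTI + JSON sidecars carrying the design
#' truth), and a cohort manifest JSON tying the files together.
#'
#' @param cohort A `healing_cohort`.
#' @param out_dir Output directory (created if needed).
#' @param days Monitoring schedule. Default [default_monitoring_schedule()].
#' @param n_treads Treads per session. Default 8.
#' @param ct Write CT volumes? Default TRUE.
#' @param spacing CT voxel spacing (mm). Default 0.3.
#' @return Invisibly, the manifest path.
#' @export
simulate_cohort <- function(cohort, out_dir,
                            days = default_monitoring_schedule(),
                            n_treads = 8, ct = TRUE, spacing = 0.3) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  animals <- lapply(cohort, function(tr) {
    trace_file <- file.path(out_dir, paste0(tr$id, "_traces.csv"))
    write_force_trace(simulate_gait_series(tr, days, n_treads = n_treads),
                      trace_file)
    truth_file <- file.path(out_dir, paste0(tr$id, "_design.csv"))
    utils::write.csv(design_state(tr, days), truth_file, row.names = FALSE)
    ct_files <- character(0)
    contra_file <- NULL
    if (ct) {
      for (d in tr$ct_days) {
        sim <- simulate_ct_volume(tr, d, spacing = spacing)
        f <- file.path(out_dir, sprintf("%s_ct_day%03d.nii.gz", tr$id, d))
        write_ct_volume(sim$volume, f, extra = list(truth = sim$truth))
        ct_files <- c(ct_files, basename(f))
      }
      sim <- simulate_ct_volume(tr, tr$sacrifice_day, limb = "contralateral",
                                spacing = spacing)
      contra_file <- file.path(out_dir, paste0(tr$id, "_ct_contralateral.nii.gz"))
      write_ct_volume(sim$volume, contra_file, extra = list(truth = sim$truth))
      contra_file <- basename(contra_file)
    }
    list(id = tr$id, body_weight = tr$body_weight, k_f = tr$k_f,
         k_bp = tr$k_bp, k_bd = tr$k_bd, k_b = tr$k_b, r_true = tr$r_true,
         sacrifice_day = tr$sacrifice_day, ct_days = tr$ct_days,
         crossover_design = design_crossover_day(tr),
         stabilization_design = design_stabilization_day(tr),
         traces = basename(trace_file), design = basename(truth_file),
         ct_volumes = ct_files, ct_contralateral = contra_file)
  })
  manifest <- list(n_animals = length(cohort), days = days,
                   n_treads = n_treads, spacing_mm = spacing,
                   animals = animals)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest_path)
}
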