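# Phantom-calibrated CT morphometry: HU -> mineral density mapping,
# mineralized-tissue segmentation, per-slice CSA/BMD profiles, total callus
# volume over the defect plus margins, and contralateral normalization.

#' Construct a voxel volume
#'
#' Container for a Hounsfield-valued CT-like grid. The third array index is
#' the longitudinal bone axis (z); voxel indices are 0-based in the external
#' convention and slice positions refer to slice centers:
#' `z_mm = z0 + (k + 0.5) * dz` for 0-based slice `k`. Spans along z are
#' half-open `[start, end)` in mm.
#'
#' @param hu 3-D numeric array of Hounsfield-like values, `[x, y, z]`.
#' @param spacing Voxel spacing `(x, y, z)` in mm/voxel, all > 0.
#' @param defect_span Optional `(z_start, z_end)` of the defect in mm.
#' @param phantoms List of phantom-insert descriptors from
#'   [phantom_cylinder()], densities within `[0, 0.8]` g HA/cm^3.
#' @param z0 Origin of the z axis (mm). Default 0.
#' @return Object of class `voxel_volume`.
#' @export
voxel_volume <- function(hu, spacing, defect_span = NULL, phantoms = list(),
                         z0 = 0) {
  stopifnot(is.array(hu), length(dim(hu)) == 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive mm/voxel values")
  if (!is.null(defect_span)) {
    zmax <- z0 + dim(hu)[3] * spacing[3]
    if (length(defect_span) != 2L || defect_span[1] >= defect_span[2] ||
        defect_span[1] < z0 || defect_span[2] > zmax)
      stop("'defect_span' must be an increasing mm pair within the volume extent")
  }
  dens <- vapply(phantoms, function(p) p$density, numeric(1))
  if (length(dens) && (any(dens < 0) || any(dens > 0.8)))
    stop("phantom densities must lie within [0, 0.8] g HA/cm^3")
  structure(list(hu = hu, spacing = as.numeric(spacing),
                 defect_span = if (is.null(defect_span)) NULL else as.numeric(defect_span),
                 phantoms = phantoms, z0 = z0),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$hu)
  cat(sprintf("Voxel volume %d x %d x %d @ (%g, %g, %g) mm, %d phantom insert(s)\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              length(x$phantoms)))
  if (!is.null(x$defect_span))
    cat(sprintf("  defect span [%g, %g) mm\n", x$defect_span[1], x$defect_span[2]))
  invisible(x)
}

#' Describe a cylindrical calibration phantom insert
#'
#' @param name Insert label.
#' @param density Known mineral density (g HA/cm^3).
#' @param center Cylinder axis position `(x, y)` in mm.
#' @param radius Cylinder radius (mm).
#' @return Phantom descriptor list.
#' @export
phantom_cylinder <- function(name, density, center, radius) {
  stopifnot(length(center) == 2L, radius > 0, density >= 0)
  list(name = name, density = density, center = as.numeric(center),
       radius = radius)
}

# voxel-center coordinate vectors (mm)
vol_x <- function(vol) (seq_len(dim(vol$hu)[1]) - 0.5) * vol$spacing[1]
vol_y <- function(vol) (seq_len(dim(vol$hu)[2]) - 0.5) * vol$spacing[2]

#' Slice-center z positions of a voxel volume (mm)
#' @param vol A `voxel_volume`.
#' @export
vol_z <- function(vol) vol$z0 + (seq_len(dim(vol$hu)[3]) - 0.5) * vol$spacing[3]

# logical [x, y] disc for one cylinder, optionally grown by margin mm
cylinder_xy <- function(vol, center, radius, margin = 0) {
  dx2 <- (vol_x(vol) - center[1])^2
  dy2 <- (vol_y(vol) - center[2])^2
  outer(dx2, dy2, "+") <= (radius + margin)^2
}

#' Voxel mask of one phantom insert
#' @param vol A `voxel_volume`.
#' @param phantom A descriptor from [phantom_cylinder()].
#' @param margin Radial growth (mm), e.g. to build exclusion zones.
#' @return Logical array of the volume's dimensions.
#' @export
phantom_mask <- function(vol, phantom, margin = 0) {
  disc <- cylinder_xy(vol, phantom$center, phantom$radius, margin)
  array(disc, dim = dim(vol$hu))
}

#' Default region of interest: everything except the phantom inserts
#'
#' @param vol A `voxel_volume`.
#' @param exclude_margin_mm Radial margin around each insert (mm). Default 2.
#' @return Logical array; `TRUE` inside the analysis ROI.
#' @export
roi_mask <- function(vol, exclude_margin_mm = 2) {
  roi <- array(TRUE, dim = dim(vol$hu))
  for (p in vol$phantoms) roi <- roi & !phantom_mask(vol, p, exclude_margin_mm)
  roi
}

#' Calibrate the HU to mineral-density mapping from phantom inserts
#'
#' Ordinary least squares of the known insert densities on the mean HU per
#' insert region: `density = intercept + slope * HU`.
#'
#' @param vol A `voxel_volume` with at least two phantom inserts of distinct
#'   density.
#' @return Object of class `calibration_line`: `slope` (g HA/cm^3 per HU),
#'   `intercept` (g HA/cm^3), `r_squared`, `n_regions`.
#' @export
calibrate_hu_to_bmd <- function(vol) {
  ph <- vol$phantoms
  if (length(ph) < 2L)
    stop("calibration requires at least two phantom regions")
  dens <- vapply(ph, function(p) p$density, numeric(1))
  if (length(unique(dens)) < 2L)
    stop("calibration requires phantoms of distinct known density")
  mu <- vapply(ph, function(p) mean(vol$hu[phantom_mask(vol, p)]), numeric(1))
  if (max(mu) - min(mu) < .Machine$double.eps^0.5)
    stop("phantom regions have identical mean HU; cannot calibrate")
  fit <- stats::lm(dens ~ mu)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration produced a non-positive slope; check phantom definitions")
  sst <- sum((dens - mean(dens))^2)
  r2 <- if (length(mu) == 2L) 1 else max(0, 1 - sum(stats::resid(fit)^2) / sst)
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n_regions = length(mu)),
            class = "calibration_line")
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf("HU -> BMD calibration: density = %.6g + %.6g * HU (R^2 = %.4f, %d inserts)\n",
              x$intercept, x$slope, x$r_squared, x$n_regions))
  invisible(x)
}

#' Map a volume's HU values to mineral densities
#' @param vol A `voxel_volume`.
#' @param calibration A `calibration_line`.
#' @return Numeric array of densities (g HA/cm^3).
#' @export
map_density <- function(vol, calibration) {
  calibration$intercept + calibration$slope * vol$hu
}

#' Segment mineralized tissue by calibrated-density thresholding
#'
#' Voxels whose mapped density reaches `density_threshold` within the region
#' of interest. The default ROI excludes the phantom inserts (plus a 2 mm
#' margin); pass a custom logical array to exclude e.g. pin-tract woven bone.
#'
#' @param vol A `voxel_volume`.
#' @param calibration A `calibration_line`.
#' @param density_threshold Minimum density (g HA/cm^3). Default 0.15.
#' @param roi Optional logical array; default [roi_mask()].
#' @return Logical mask array with `spacing` and `z0` attributes; an empty
#'   mask is allowed.
#' @export
segment_mineralized <- function(vol, calibration, density_threshold = 0.15,
                                roi = NULL) {
  if (is.null(roi)) roi <- roi_mask(vol)
  stopifnot(identical(dim(roi), dim(vol$hu)))
  mask <- (map_density(vol, calibration) >= density_threshold) & roi
  attr(mask, "spacing") <- vol$spacing
  attr(mask, "z0") <- vol$z0
  mask
}

#' Per-slice mineralized cross-sectional area
#'
#' @param mask Binary mask from [segment_mineralized()] (or any logical
#'   array with the same layout).
#' @param spacing Voxel spacing (mm); defaults to the mask's attribute.
#' @param z0 z-axis origin (mm); defaults to the mask's attribute.
#' @return Data frame with `z_mm` (slice centers) and `csa_mm2`.
#' @export
csa_profile <- function(mask, spacing = attr(mask, "spacing"),
                        z0 = attr(mask, "z0")) {
  stopifnot(length(dim(mask)) == 3L, length(spacing) == 3L)
  if (is.null(z0)) z0 <- 0
  counts <- apply(mask, 3, sum)
  data.frame(z_mm = z0 + (seq_along(counts) - 0.5) * spacing[3],
             csa_mm2 = counts * spacing[1] * spacing[2])
}

# half-open span membership for slice centers
in_span <- function(z, span) z >= span[1] - 1e-9 & z < span[2] - 1e-9

#' Total mineralized volume over the defect plus margins
#'
#' Integrates the CSA profile over `[z_start - margin, z_end + margin)` by
#' the rectangle rule and converts to cm^3. A window reaching outside the
#' scanned extent is clipped with a warning.
#'
#' @param profile CSA profile from [csa_profile()].
#' @param defect_span `(z_start, z_end)` in mm.
#' @param margin Extra tissue included on each side (mm). Default 10.
#' @return Total volume (cm^3).
#' @export
total_volume <- function(profile, defect_span, margin = 10) {
  stopifnot(all(c("z_mm", "csa_mm2") %in% names(profile)),
            length(defect_span) == 2L, defect_span[1] < defect_span[2],
            margin >= 0)
  win <- c(defect_span[1] - margin, defect_span[2] + margin)
  dz <- if (nrow(profile) > 1L) stats::median(diff(profile$z_mm)) else NA_real_
  zlo <- min(profile$z_mm) - dz / 2
  zhi <- max(profile$z_mm) + dz / 2
  if (win[1] < zlo - 1e-9 || win[2] > zhi + 1e-9)
    warning("TV window [", win[1], ", ", win[2],
            ") extends outside the scanned extent; clipped")
  sel <- in_span(profile$z_mm, win)
  sum(profile$csa_mm2[sel] * dz) / 1000
}

#' Per-slice and summary bone mineral density
#'
#' Mean calibrated density over the masked voxels of each slice; slices with
#' an empty mask yield `NA`, not zero. The summary is the voxel-wise mean
#' density over the defect span.
#'
#' @param vol A `voxel_volume`.
#' @param mask Segmentation mask.
#' @param calibration A `calibration_line`.
#' @param defect_span Span for the summary; defaults to the volume's.
#' @return List with `profile` (data frame `z_mm`, `bmd_g_cm3`) and
#'   `summary_g_cm3` (scalar, `NA` with a warning if the mask is empty over
#'   the span).
#' @export
bmd_profile <- function(vol, mask, calibration, defect_span = vol$defect_span) {
  stopifnot(identical(dim(mask)[1:3], dim(vol$hu)))
  dens <- map_density(vol, calibration)
  nz <- dim(vol$hu)[3]
  z <- vol_z(vol)
  slice_bmd <- vapply(seq_len(nz), function(k) {
    m <- mask[, , k]
    if (!any(m)) NA_real_ else mean(dens[, , k][m])
  }, numeric(1))
  summary_val <- NA_real_
  if (!is.null(defect_span)) {
    sel <- which(in_span(z, defect_span))
    msel <- mask[, , sel, drop = FALSE]
    if (!any(msel)) {
      warning("segmentation mask is empty over the defect span; BMD summary is NA")
    } else {
      summary_val <- mean(dens[, , sel, drop = FALSE][msel])
    }
  }
  list(profile = data.frame(z_mm = z, bmd_g_cm3 = slice_bmd),
       summary_g_cm3 = summary_val)
}

#' Full morphometry of one calibrated volume
#'
#' Calibrates (unless a line is supplied), segments, and reduces a volume to
#' the standard morphometric summary: per-slice CSA/BMD profiles, mean CSA
#' and voxel-mean BMD over the defect span, and total volume over the defect
#' plus margins.
#'
#' @param vol A `voxel_volume` with a defect span.
#' @param calibration Optional `calibration_line`; computed from the
#'   volume's phantoms when `NULL`.
#' @param density_threshold Segmentation threshold (g HA/cm^3).
#' @param margin TV margin on each side of the defect (mm). Default 10.
#' @param roi Optional ROI mask passed to [segment_mineralized()].
#' @return Object of class `morphometry`: `profile` (z_mm, csa_mm2,
#'   bmd_g_cm3), `tv_cm3`, `csa_mm2` (defect-span mean), `bmd_g_cm3`
#'   (defect-span voxel mean), `defect_span`, `margin`, `calibration`.
#' @export
morphometry_summary <- function(vol, calibration = NULL,
                                density_threshold = 0.15, margin = 10,
                                roi = NULL) {
  if (is.null(vol$defect_span)) stop("volume has no defect span")
  if (is.null(calibration)) calibration <- calibrate_hu_to_bmd(vol)
  mask <- segment_mineralized(vol, calibration, density_threshold, roi)
  csa <- csa_profile(mask)
  bmd <- bmd_profile(vol, mask, calibration)
  sel <- in_span(csa$z_mm, vol$defect_span)
  structure(list(
    profile = data.frame(z_mm = csa$z_mm, csa_mm2 = csa$csa_mm2,
                         bmd_g_cm3 = bmd$profile$bmd_g_cm3),
    tv_cm3 = total_volume(csa, vol$defect_span, margin),
    csa_mm2 = mean(csa$csa_mm2[sel]),
    bmd_g_cm3 = bmd$summary_g_cm3,
    defect_span = vol$defect_span, margin = margin,
    calibration = calibration), class = "morphometry")
}

#' @export
print.morphometry <- function(x, ...) {
  cat(sprintf("Morphometry: TV = %.3f cm^3, defect-span CSA = %.2f mm^2, BMD = %.3f g HA/cm^3\n",
              x$tv_cm3, x$csa_mm2, x$bmd_g_cm3))
  invisible(x)
}

#' Normalize treated-limb morphometry to the contralateral control
#'
#' Expresses TV, CSA and BMD as percentages of the non-operated
#' contralateral limb. By convention the control values are taken over the
#' 15 mm defect-equivalent span only (the control TV is mean CSA times span
#' length, without margins), while the treated TV includes the margins.
#'
#' @param treated,control `morphometry` objects (or lists with `tv_cm3`,
#'   `csa_mm2`, `bmd_g_cm3`).
#' @return One-row data frame: `tv_pct`, `csa_pct`, `bmd_pct`.
#' @export
normalize_to_contralateral <- function(treated, control) {
  vals_c <- c(control$tv_cm3, control$csa_mm2, control$bmd_g_cm3)
  if (any(!is.finite(vals_c)) || any(vals_c == 0))
    stop("control morphometry contains zero or missing values")
  data.frame(tv_pct = 100 * treated$tv_cm3 / control$tv_cm3,
             csa_pct = 100 * treated$csa_mm2 / control$csa_mm2,
             bmd_pct = 100 * treated$bmd_g_cm3 / control$bmd_g_cm3)
}

#' Write / read a voxel volume as NIfTI plus a JSON sidecar
#'
#' The HU grid goes to a `.nii.gz` with the voxel spacing in the header;
#' the defect span, z origin and phantom-insert definitions go to a sidecar
#' `<path>.json` (the NIfTI format carries none of these).
#'
#' @param vol A `voxel_volume`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param extra Optional named list merged into the sidecar (e.g. ground
#'   truth from a simulator).
#' @return `write_ct_volume` invisibly returns `path`; `read_ct_volume`
#'   returns a list with `volume` and `sidecar`.
#' @export
write_ct_volume <- function(vol, path, extra = NULL) {
  img <- RNifti::asNifti(vol$hu)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  side <- list(spacing_mm = vol$spacing, z0_mm = vol$z0,
               defect_span_mm = vol$defect_span,
               phantoms = vol$phantoms)
  if (!is.null(extra)) side <- c(side, extra)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")

#' @rdname write_ct_volume
#' @export
read_ct_volume <- function(path) {
  img <- RNifti::readNifti(path)
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  phantoms <- side$phantoms
  if (is.data.frame(phantoms)) {
    phantoms <- lapply(seq_len(nrow(phantoms)), function(i)
      phantom_cylinder(phantoms$name[i], phantoms$density[i],
                       unlist(phantoms$center[i]), phantoms$radius[i]))
  }
  vol <- voxel_volume(hu = array(as.numeric(img), dim = dim(img)),
                      spacing = unlist(side$spacing_mm),
                      defect_span = if (is.null(side$defect_span_mm)) NULL
                                    else unlist(side$defect_span_mm),
                      phantoms = if (is.null(phantoms)) list() else phantoms,
                      z0 = side$z0_mm %||% 0)
  list(volume = vol, sidecar = side)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
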