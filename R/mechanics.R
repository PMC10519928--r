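# Bone-fixator spring-network mechanics.
#
# The operated limb is modeled as an axial spring network: the external
# fixator (stiffness K_f) bridges the defect in parallel with the bone path,
# in which the regenerating callus (K_c) sits in series with the proximal and
# distal cortical fragments (K_bp, K_bd; equivalent series stiffness K_b).
# During stance the internal metatarsal force F_i splits into a fixator
# component F_f (measured by the instrumented connecting bars) and a callus
# component F_c = F_i - F_f. All stiffnesses are in N/mm, forces in N.

#' Equivalent stiffness of two springs in series
#'
#' Combines the proximal and distal cortical fragment stiffnesses into the
#' single equivalent cortical stiffness `K_b = K_bp * K_bd / (K_bp + K_bd)`.
#'
#' @param k_bp Proximal fragment axial stiffness (N/mm), positive.
#' @param k_bd Distal fragment axial stiffness (N/mm), positive.
#' @return Equivalent stiffness (N/mm); always strictly below `min(k_bp, k_bd)`.
#' @examples
#' series_equivalent_stiffness(309850, 356740) / 1000 # 165.82 kN/mm
#' @export
series_equivalent_stiffness <- function(k_bp, k_bd) {
  if (any(!is.finite(k_bp)) || any(k_bp <= 0))
    stop("'k_bp' must be a positive, finite stiffness (N/mm)")
  if (any(!is.finite(k_bd)) || any(k_bd <= 0))
    stop("'k_bd' must be a positive, finite stiffness (N/mm)")
  k_bp * k_bd / (k_bp + k_bd)
}

#' Axial stiffness of a varying-section rod from a cross-sectional area profile
#'
#' Treats a bone fragment as a straight rod loaded axially: slices of area
#' `A(z)` and thickness `dz` act as springs in series, so
#' `K = 1 / sum(dz / (E * A(z)))`. For a uniform section this reduces to
#' `E * A / L`.
#'
#' @param area_mm2 Per-slice mineralized cross-sectional area (mm^2), all > 0.
#' @param dz_mm Slice thickness (mm); scalar or one value per slice.
#' @param modulus_mpa Cortical elastic modulus (MPa). Default 21000 (21 GPa).
#' @return Axial stiffness in N/mm.
#' @export
cortical_stiffness_from_profile <- function(area_mm2, dz_mm, modulus_mpa = 21000) {
  if (length(area_mm2) < 1L) stop("need at least one slice")
  bad <- which(!is.finite(area_mm2) | area_mm2 <= 0)
  if (length(bad))
    stop("non-positive cross-sectional area at slice index ", bad[1L])
  if (any(!is.finite(dz_mm)) || any(dz_mm <= 0)) stop("'dz_mm' must be positive")
  if (!is.finite(modulus_mpa) || modulus_mpa <= 0) stop("'modulus_mpa' must be positive")
  dz <- rep_len(dz_mm, length(area_mm2))
  1 / sum(dz / (modulus_mpa * area_mm2))
}

#' Callus force from the force balance
#'
#' The internal force splits between the fixator and the callus, so the
#' callus carries `F_c = F_i - F_f`. Negative results are permitted (they
#' arise from measurement noise early in healing) and are flagged downstream.
#'
#' @param f_i Internal metatarsal force (N).
#' @param f_f Force through the fixator (N).
#' @return Callus force (N).
#' @export
callus_force <- function(f_i, f_f) {
  stopifnot(is.numeric(f_i), is.numeric(f_f))
  f_i - f_f
}

#' Apparent callus stiffness from the measured force partition
#'
#' Lumped axial stiffness attributed to the regenerate,
#' `K_c = K_f * F_c * K_b / (F_f * K_b + F_c * K_f)`,
#' assuming homogeneous tissue properties and a common system displacement.
#' Vectorized over forces. Stances where `f_f <= 0` or `f_c <= 0` fall
#' outside the model's validity (fixator unloaded, or no callus load) and
#' yield `NA` rather than a number; callers apply the measurement-range
#' censoring rule on top (see [estimate_callus_stiffness()]).
#'
#' @param f_f Fixator force (N).
#' @param f_c Callus force (N).
#' @param k_f Fixator stiffness (N/mm).
#' @param k_b Equivalent cortical stiffness (N/mm).
#' @return Apparent callus stiffness (N/mm), `NA` where invalid.
#' @export
callus_stiffness <- function(f_f, f_c, k_f, k_b) {
  if (any(!is.finite(k_f)) || any(k_f <= 0)) stop("'k_f' must be positive")
  if (any(!is.finite(k_b)) || any(k_b <= 0)) stop("'k_b' must be positive")
  out <- k_f * (f_c * k_b) / (f_f * k_b + f_c * k_f)
  out[!is.finite(f_f) | !is.finite(f_c) | f_f <= 0 | f_c <= 0] <- NA_real_
  out
}

#' Forward load partition for a known callus stiffness
#'
#' Exact algebraic inverse of the callus-stiffness estimator: given the
#' internal force and the component stiffnesses, returns the unique fixator
#' and callus forces consistent with the spring-network model. The fixator
#' load-share fraction is
#' `lambda = K_f * (K_b - K_c) / (K_c * K_b + K_f * (K_b - K_c))`,
#' which is 1 at `K_c = 0`, strictly decreasing in `K_c`, and 1/2 at
#' `K_c = K_f * K_b / (K_b + K_f)` (the crossover stiffness).
#'
#' @param f_i Internal force (N), non-negative. Vectorized with `k_c`.
#' @param k_c Callus stiffness (N/mm), `0 <= k_c < k_b`.
#' @param k_f Fixator stiffness (N/mm).
#' @param k_b Equivalent cortical stiffness (N/mm).
#' @return A list with components `f_f` and `f_c` (N), `f_f + f_c == f_i`.
#' @export
forward_load_partition <- function(f_i, k_c, k_f, k_b) {
  if (any(!is.finite(k_f)) || any(k_f <= 0)) stop("'k_f' must be positive")
  if (any(!is.finite(k_b)) || any(k_b <= 0)) stop("'k_b' must be positive")
  if (any(!is.finite(k_c)) || any(k_c < 0)) stop("'k_c' must be >= 0")
  if (any(k_c >= k_b))
    stop("'k_c' must be below 'k_b': the model is only valid while the callus ",
         "is softer than the intact cortical path")
  if (any(f_i < 0)) stop("'f_i' must be non-negative")
  lambda <- k_f * (k_b - k_c) / (k_c * k_b + k_f * (k_b - k_c))
  f_f <- lambda * f_i
  list(f_f = f_f, f_c = f_i - f_f)
}

#' Fixator load-share fraction
#'
#' Fraction of the internal force carried by the fixator, `F_f / F_i`.
#' Values near 1 indicate an unbridged defect; the decay toward 0 tracks
#' mechanical healing.
#'
#' @param f_f Fixator force (N).
#' @param f_i Internal force (N), strictly positive.
#' @return Dimensionless fraction (typically in `[0, 1]`).
#' @export
load_share_fraction <- function(f_f, f_i) {
  if (any(!is.finite(f_i)) || any(f_i <= 0)) stop("'f_i' must be positive")
  f_f / f_i
}

#' Calibrate the internal-force to ground-reaction-force ratio
#'
#' During the early latency/consolidation window there is essentially no
#' mineralized bridge, so the fixator carries the internal force
#' (`F_i ~ F_f`). The constant ratio `r = F_i / GRF` is therefore estimated
#' as the mean of `F_f / GRF` over per-tread peak pairs inside the window,
#' and reused for the whole follow-up.
#'
#' @param peaks Data frame of per-tread peak pairs with columns `day`,
#'   `grf` and `ff` (N), e.g. from [peak_per_tread()].
#' @param window Calibration window in days post-surgery, half-open
#'   `[window[1], window[2])`. Default `c(7, 14)`.
#' @return An object of class `calibration_ratio`: list with `r`, `window`,
#'   `n_samples`.
#' @export
calibrate_force_ratio <- function(peaks, window = c(7, 14)) {
  stopifnot(is.data.frame(peaks), all(c("day", "grf", "ff") %in% names(peaks)))
  if (length(window) != 2L || window[1] >= window[2])
    stop("'window' must be an increasing (start, end) day pair")
  sel <- peaks$day >= window[1] & peaks$day < window[2]
  inw <- peaks[sel, , drop = FALSE]
  if (nrow(inw) == 0L)
    stop("no treads inside the calibration window [", window[1], ", ",
         window[2], ")")
  bad <- inw$grf <= 0 | !is.finite(inw$grf)
  if (any(bad)) {
    warning(sum(bad), " tread(s) with non-positive GRF skipped during calibration")
    inw <- inw[!bad, , drop = FALSE]
  }
  if (nrow(inw) == 0L) stop("all in-window treads had non-positive GRF")
  structure(
    list(r = mean(inw$ff / inw$grf), window = as.numeric(window),
         n_samples = nrow(inw)),
    class = "calibration_ratio")
}

#' @export
print.calibration_ratio <- function(x, ...) {
  cat(sprintf("Internal-force calibration: r = F_i/GRF = %.4f (n = %d treads, days [%g, %g))\n",
              x$r, x$n_samples, x$window[1], x$window[2]))
  invisible(x)
}

#' Assemble the per-animal stiffness set
#'
#' @param k_bp,k_bd Proximal/distal fragment stiffnesses (N/mm).
#' @param k_f Fixator axial stiffness (N/mm); default 593.
#' @param modulus_mpa Cortical modulus used when fragments were derived from
#'   CT geometry (MPa); stored for provenance.
#' @return `stiffness_set` object with derived equivalent stiffness `k_b`.
#' @export
stiffness_set <- function(k_bp, k_bd, k_f = 593, modulus_mpa = 21000) {
  k_b <- series_equivalent_stiffness(k_bp, k_bd)
  if (!is.finite(k_f) || k_f <= 0) stop("'k_f' must be positive")
  structure(list(k_f = k_f, k_bp = k_bp, k_bd = k_bd, k_b = k_b,
                 modulus_mpa = modulus_mpa),
            class = "stiffness_set")
}

#' @export
print.stiffness_set <- function(x, ...) {
  cat(sprintf("Stiffness set (N/mm): K_f = %g, K_bp = %g, K_bd = %g, K_b = %g\n",
              x$k_f, x$k_bp, x$k_bd, x$k_b))
  invisible(x)
}

#' Reference fragment stiffnesses for the ovine metatarsus cohort
#'
#' Published per-animal estimates of the proximal and distal cortical
#' fragment stiffnesses (from CT geometry at a 21 GPa modulus) together with
#' the printed equivalent cortical stiffness, for eight sheep, plus their
#' consolidation endpoints and CT time-points. Values in kN/mm. The printed
#' `kb_kn_mm` of animal S5 disagrees with the series formula by 0.34 kN/mm
#' (probable transcription error); `kb_series_kn_mm` carries the recomputed
#' value and `kb_consistent` flags the discrepancy.
#'
#' @return Data frame with one row per animal: `id`, `sacrifice_day`,
#'   `ct_days` (list column), `kbp_kn_mm`, `kbd_kn_mm`, `kb_kn_mm` (as
#'   printed), `kb_series_kn_mm`, `kb_consistent`.
#' @export
ovine_stiffness_reference <- function() {
  tab <- data.frame(
    id = paste0("S", 1:8),
    sacrifice_day = c(365, 219, 194, 152, 123, 65, 51, 30),
    kbp_kn_mm = c(309.85, 144.51, 199.86, 173.25, 236.96, 160.67, 206.71, 218.43),
    kbd_kn_mm = c(356.74, 138.36, 206.13, 190.27, 333.16, 136.69, 219.49, 236.98),
    kb_kn_mm  = c(165.82, 70.68, 101.47, 90.68, 138.13, 73.86, 106.45, 113.67),
    stringsAsFactors = FALSE)
  tab$ct_days <- list(c(365, 285, 176), 219, c(194, 158), 152, 123, 65, 51, 30)
  tab$kb_series_kn_mm <- series_equivalent_stiffness(tab$kbp_kn_mm, tab$kbd_kn_mm)
  tab$kb_consistent <- abs(tab$kb_series_kn_mm - tab$kb_kn_mm) <= 0.01
  tab
}

#' Estimate a (possibly censored) callus-stiffness series
#'
#' Applies the callus-stiffness estimator to daily force data with the
#' measurement-range guard: when the fixator is essentially unloaded
#' (`f_f < censor_frac * f_i`, default 2%) the stiffness estimate lies
#' outside the calibrated range of the load cells and is reported as
#' right-censored rather than numeric. Stances with non-positive callus
#' force (no bridging yet, or noise) are invalid.
#'
#' @param f_f,f_i Fixator and internal forces (N), vectors of equal length.
#' @param k_f,k_b Fixator and equivalent cortical stiffnesses (N/mm).
#' @param censor_frac Censoring threshold as a fraction of `f_i`. Default 0.02.
#' @return Data frame with columns `k_c` (N/mm, `NA` when not numeric),
#'   `censored` (logical: estimate beyond measurement range) and `valid`
#'   (logical: numeric estimate available).
#' @export
estimate_callus_stiffness <- function(f_f, f_i, k_f, k_b, censor_frac = 0.02) {
  stopifnot(length(f_f) == length(f_i))
  if (!is.finite(censor_frac) || censor_frac < 0) stop("'censor_frac' must be >= 0")
  f_c <- callus_force(f_i, f_f)
  censored <- is.finite(f_f) & is.finite(f_i) & f_f < censor_frac * f_i
  k_c <- callus_stiffness(f_f, f_c, k_f, k_b)
  k_c[censored] <- NA_real_
  data.frame(k_c = k_c, censored = censored,
             valid = !censored & is.finite(k_c))
}
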