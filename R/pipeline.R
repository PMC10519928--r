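# End-to-end analysis: traces -> calibration -> force partition -> callus
# stiffness series -> crossover/stabilization; CT volumes -> morphometry ->
# contralateral percentages; cohort report.

#' Analyze one animal's gait and mechanics
#'
#' Runs the full mechanical pipeline on a multi-day force-trace table:
#' stance detection and per-tread peaks, internal-force ratio calibration in
#' the early window, daily force partition (`F_i = r * GRF`,
#' `F_c = F_i - F_f`), censored callus-stiffness estimation, and
#' crossover/stabilization detection.
#'
#' @param traces Trace data frame (columns `day`, `tread_id`, `t`, `grf_N`,
#'   `ff_N`) or a path to a trace CSV.
#' @param k_f Fixator stiffness (N/mm).
#' @param k_b Equivalent cortical stiffness (N/mm).
#' @param body_weight Body weight (kg).
#' @param calibration_window Early window for the `F_i/GRF` ratio (days,
#'   half-open). Default `c(7, 14)`.
#' @param censor_frac Measurement-range censoring threshold on
#'   `F_f / F_i`. Default 0.02.
#' @param healthy_fraction Healthy GRF as a fraction of body weight.
#'   Default 0.425.
#' @param stab_band_frac Stabilization band as a fraction of the mean
#'   internal force. Default 0.05.
#' @param stab_hold_days Stabilization hold (days). Default 14.
#' @return Object of class `animal_analysis`: `ratio`
#'   (`calibration_ratio`), `peaks`, `daily` (day, n_treads, grf_N, ff_N,
#'   grf_pct, complete, f_i, f_c, k_c, censored, valid), `crossover_day`,
#'   `stabilization_day`.
#' @export
analyze_animal <- function(traces, k_f, k_b, body_weight,
                           calibration_window = c(7, 14), censor_frac = 0.02,
                           healthy_fraction = 0.425, stab_band_frac = 0.05,
                           stab_hold_days = 14) {
  if (is.character(traces)) traces <- read_force_trace(traces)
  peaks <- extract_tread_peaks(traces, body_weight)
  ratio <- calibrate_force_ratio(peaks, calibration_window)
  daily <- do.call(rbind, lapply(split(peaks, peaks$day), daily_summary,
                                 body_weight_kg = body_weight,
                                 healthy_fraction = healthy_fraction))
  daily <- daily[order(daily$day), , drop = FALSE]
  rownames(daily) <- NULL
  daily$f_i <- ratio$r * daily$grf_N
  daily$f_c <- callus_force(daily$f_i, daily$ff_N)
  kc <- estimate_callus_stiffness(daily$ff_N, daily$f_i, k_f, k_b,
                                  censor_frac)
  daily <- cbind(daily, kc)
  structure(list(
    ratio = ratio, peaks = peaks, daily = daily,
    crossover_day = detect_crossover_day(daily$day, daily$ff_N, daily$f_c),
    stabilization_day = detect_stabilization(
      daily$day, daily$ff_N, band = stab_band_frac * mean(daily$f_i),
      hold_days = stab_hold_days),
    k_f = k_f, k_b = k_b, body_weight = body_weight),
    class = "animal_analysis")
}

#' @export
print.animal_analysis <- function(x, ...) {
  cat(sprintf(
    "Animal analysis: %d monitoring day(s), r = %.4f, crossover day %.1f, stabilization day %s\n",
    nrow(x$daily), x$ratio$r, x$crossover_day,
    if (is.na(x$stabilization_day)) "not reached" else
      sprintf("%.0f", x$stabilization_day)))
  invisible(x)
}

#' Look up the estimated callus stiffness on a given day
#'
#' @param analysis An `animal_analysis`.
#' @param day Monitoring day (must be in the analyzed series).
#' @return Stiffness (N/mm); `NA` if censored/invalid on that day.
#' @export
kc_on_day <- function(analysis, day) {
  i <- match(day, analysis$daily$day)
  if (is.na(i)) stop("day ", day, " was not monitored")
  analysis$daily$k_c[i]
}

#' Analyze a simulated (or recorded) cohort directory
#'
#' Reads a cohort manifest written by [simulate_cohort()] (or hand-built to
#' the same schema), runs [analyze_animal()] per animal, processes every CT
#' volume through [morphometry_summary()] with contralateral normalization,
#' pairs GRF with BMD at CT time-points, and fits the GRF-BMD regression.
#'
#' @param manifest_path Path to `manifest.json`.
#' @param out_dir Optional directory for tidy outputs: per-animal daily CSV,
#'   cohort CT summary CSV, and a cohort summary JSON.
#' @param grf_scale GRF normalization for the regression: `"pct_bw"`
#'   (percent of body weight, default) or `"pct_healthy"`.
#' @param ... Passed to [analyze_animal()].
#' @return Object of class `cohort_analysis`: `animals` (named list of
#'   `animal_analysis`), `ct` (data frame of morphometry and percentages),
#'   `regression` (or `NULL` when too few CT points), `summary` (per-animal
#'   crossover/stabilization/ratio table).
#' @export
analyze_cohort_dir <- function(manifest_path, out_dir = NULL,
                               grf_scale = c("pct_bw", "pct_healthy"), ...) {
  grf_scale <- match.arg(grf_scale)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  base <- dirname(manifest_path)
  animals <- list()
  ct_rows <- list()
  for (a in manifest$animals) {
    an <- analyze_animal(file.path(base, a$traces),
                         k_f = a$k_f, k_b = a$k_b,
                         body_weight = a$body_weight, ...)
    animals[[a$id]] <- an
    if (length(a$ct_volumes)) {
      control <- NULL
      if (!is.null(a$ct_contralateral)) {
        cv <- read_ct_volume(file.path(base, a$ct_contralateral))
        control <- morphometry_summary(cv$volume, margin = 0)
      }
      for (f in a$ct_volumes) {
        tv <- read_ct_volume(file.path(base, f))
        m <- morphometry_summary(tv$volume)
        day <- tv$sidecar$truth$day %||%
          as.numeric(sub(".*day([0-9]+).*", "\\1", f))
        row <- data.frame(id = a$id, day = day, tv_cm3 = m$tv_cm3,
                          csa_mm2 = m$csa_mm2, bmd_g_cm3 = m$bmd_g_cm3)
        if (!is.null(control)) row <- cbind(row, normalize_to_contralateral(m, control))
        ct_rows[[length(ct_rows) + 1L]] <- row
      }
    }
  }
  ct <- if (length(ct_rows)) do.call(rbind, ct_rows) else NULL

  regression <- NULL
  if (!is.null(ct) && nrow(ct) >= 3L) {
    pairs <- do.call(rbind, lapply(seq_len(nrow(ct)), function(i) {
      an <- animals[[ct$id[i]]]
      j <- which.min(abs(an$daily$day - ct$day[i]))
      if (abs(an$daily$day[j] - ct$day[i]) > 14) return(NULL)
      grf <- if (grf_scale == "pct_bw")
        100 * an$daily$grf_N[j] / (an$body_weight * GRAVITY)
      else an$daily$grf_pct[j]
      data.frame(grf = grf, bmd = ct$bmd_g_cm3[i])
    }))
    if (!is.null(pairs) && nrow(pairs) >= 3L)
      regression <- grf_bmd_regression(pairs$grf, pairs$bmd)
  }

  summary_tab <- do.call(rbind, lapply(names(animals), function(id) {
    an <- animals[[id]]
    data.frame(id = id, r = an$ratio$r, n_calibration = an$ratio$n_samples,
               crossover_day = as.numeric(an$crossover_day),
               stabilization_day = as.numeric(an$stabilization_day))
  }))

  res <- structure(list(animals = animals, ct = ct, regression = regression,
                        summary = summary_tab), class = "cohort_analysis")
  if (!is.null(out_dir)) write_cohort_outputs(res, out_dir)
  res
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("Cohort analysis: %d animal(s), mean crossover day %.1f\n",
              length(x$animals), mean(x$summary$crossover_day, na.rm = TRUE)))
  if (!is.null(x$regression)) print(x$regression)
  invisible(x)
}

# tidy CSV/JSON outputs for a cohort analysis
write_cohort_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(res$animals)) {
    utils::write.csv(res$animals[[id]]$daily,
                     file.path(out_dir, paste0(id, "_daily.csv")),
                     row.names = FALSE)
  }
  utils::write.csv(res$summary, file.path(out_dir, "cohort_mechanics.csv"),
                   row.names = FALSE)
  if (!is.null(res$ct))
    utils::write.csv(res$ct, file.path(out_dir, "cohort_ct.csv"),
                     row.names = FALSE)
  summ <- list(
    mean_crossover_day = mean(res$summary$crossover_day, na.rm = TRUE),
    mean_stabilization_day = mean(res$summary$stabilization_day, na.rm = TRUE),
    mean_ratio = mean(res$summary$r),
    regression = if (!is.null(res$regression))
      res$regression[c("slope", "intercept", "r_squared", "p_value", "n",
                       "significant")])
  jsonlite::write_json(summ, file.path(out_dir, "cohort_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Write a human-readable cohort report
#'
#' Markdown summary of the mechanical and imaging monitoring: per-animal
#' calibration ratio, crossover and stabilization days, callus-stiffness
#' milestones (censored entries rendered as `>range`), and CT percentages.
#'
#' @param res A `cohort_analysis`.
#' @param path Output path (Markdown).
#' @return Invisibly, `path`.
#' @export
write_cohort_report <- function(res, path) {
  lines <- c("# Cohort monitoring report", "",
             sprintf("Animals analyzed: %d", length(res$animals)), "",
             "## Mechanics", "",
             "| animal | F_i/GRF ratio | crossover day | stabilization day |",
             "|---|---|---|---|")
  for (i in seq_len(nrow(res$summary))) {
    s <- res$summary[i, ]
    lines <- c(lines, sprintf("| %s | %.4f | %s | %s |", s$id,
                              s$r,
                              ifelse(is.na(s$crossover_day), "not reached",
                                     sprintf("%.1f", s$crossover_day)),
                              ifelse(is.na(s$stabilization_day), "not reached",
                                     sprintf("%.0f", s$stabilization_day))))
  }
  lines <- c(lines, "", "## Callus stiffness (N/mm) at milestones", "",
             "| animal | day 40 | day 60 |", "|---|---|---|")
  fmt_kc <- function(an, d) {
    i <- match(d, an$daily$day)
    if (is.na(i)) return("-")
    if (an$daily$censored[i]) return(">range")
    if (!an$daily$valid[i]) return("invalid")
    sprintf("%.0f", an$daily$k_c[i])
  }
  for (id in names(res$animals)) {
    an <- res$animals[[id]]
    lines <- c(lines, sprintf("| %s | %s | %s |", id,
                              fmt_kc(an, 40), fmt_kc(an, 60)))
  }
  if (!is.null(res$ct)) {
    lines <- c(lines, "", "## CT morphometry", "",
               "| animal | day | TV (cm^3) | CSA (mm^2) | BMD (g HA/cm^3) | TV% | CSA% | BMD% |",
               "|---|---|---|---|---|---|---|---|")
    for (i in seq_len(nrow(res$ct))) {
      r <- res$ct[i, ]
      pct <- function(v) if (is.null(r[[v]]) || is.na(r[[v]])) "-" else sprintf("%.1f", r[[v]])
      lines <- c(lines, sprintf("| %s | %g | %.2f | %.1f | %.3f | %s | %s | %s |",
                                r$id, r$day, r$tv_cm3, r$csa_mm2, r$bmd_g_cm3,
                                pct("tv_pct"), pct("csa_pct"), pct("bmd_pct")))
    }
  }
  if (!is.null(res$regression)) {
    rg <- res$regression
    lines <- c(lines, "", "## GRF-BMD regression", "",
               sprintf("slope = %.4g, intercept = %.4g, R^2 = %.3f, p = %.3g, n = %d (%s)",
                       rg$slope, rg$intercept, rg$r_squared, rg$p_value, rg$n,
                       if (rg$significant) "significant (R^2 > 0.5, p < 0.005)"
                       else "not significant"))
  }
  writeLines(lines, path)
  invisible(path)
}
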