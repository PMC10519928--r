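# Time-course statistics: load-share crossover, stabilization detection,
# recovery-curve fitting, and the GRF-BMD regression with the study's
# significance criterion (R^2 > 0.5 and p < 0.005).

#' First day the callus out-loads the fixator
#'
#' Finds the first day `d` with `F_c(d) > F_f(d)`, linearly interpolating
#' the difference `F_c - F_f` between the bracketing sampling days to give a
#' fractional crossover day. Rows with missing forces are dropped. The
#' result is invariant to a common positive rescaling of both forces.
#'
#' @param day Sampling days, strictly increasing.
#' @param f_f Fixator force (N) per day.
#' @param f_c Callus force (N) per day.
#' @return Fractional crossover day, or `NA` with a `"reason"` attribute if
#'   the forces never cross.
#' @export
detect_crossover_day <- function(day, f_f, f_c) {
  stopifnot(length(day) == length(f_f), length(day) == length(f_c))
  keep <- is.finite(day) & is.finite(f_f) & is.finite(f_c)
  day <- day[keep]; f_f <- f_f[keep]; f_c <- f_c[keep]
  if (length(day) < 2L)
    return(structure(NA_real_, reason = "fewer than two usable days"))
  if (is.unsorted(day, strictly = TRUE)) stop("'day' must be strictly increasing")
  diffc <- f_c - f_f
  if (diffc[1] > 0) return(day[1])
  idx <- which(diffc > 0)
  if (!length(idx))
    return(structure(NA_real_, reason = "callus force never exceeds fixator force"))
  i <- idx[1]
  # linear interpolation of the sign change between day[i-1] and day[i]
  d0 <- day[i - 1]; d1 <- day[i]
  y0 <- diffc[i - 1]; y1 <- diffc[i]
  d0 + (0 - y0) / (y1 - y0) * (d1 - d0)
}

#' Detect stabilization of a monitored quantity
#'
#' First sampling day from which the quantity stays inside
#' `[center - band, center + band]` through the end of the record, provided
#' the record extends at least `hold_days` beyond that day. The default use
#' is fixator-force stabilization around zero with a band of 5% of the mean
#' internal force and a 14-day hold.
#'
#' @param day Sampling days, strictly increasing.
#' @param x Quantity per day.
#' @param band Half-width of the tolerance band (same units as `x`).
#' @param hold_days Minimum observed in-band duration (days). Default 14.
#' @param center Band center. Default 0.
#' @return Stabilization day, or `NA` with a `"reason"` attribute.
#' @export
detect_stabilization <- function(day, x, band, hold_days = 14, center = 0) {
  stopifnot(length(day) == length(x), band > 0, hold_days >= 0)
  keep <- is.finite(day) & is.finite(x)
  day <- day[keep]; x <- x[keep]
  if (length(day) == 0L || max(day) - min(day) < hold_days) {
    warning("series shorter than the hold window; stabilization undetermined")
    return(structure(NA_real_, reason = "series shorter than hold window"))
  }
  inside <- abs(x - center) <= band
  # last run of in-band samples extending to the end of the record
  if (!inside[length(inside)])
    return(structure(NA_real_, reason = "not inside the band at end of record"))
  first_bad <- max(c(0L, which(!inside)))
  d <- day[first_bad + 1L]
  if (max(day) - d < hold_days)
    return(structure(NA_real_, reason = "in-band duration shorter than hold"))
  d
}

#' Fit a recovery trend curve
#'
#' Least-squares fit of one of three monotone-trend families used to
#' summarize healing time-courses:
#' \describe{
#'   \item{`exp_saturation`}{`A - B * exp(-t / tau)`}
#'   \item{`logistic`}{`A / (1 + exp(-(t - t0) / s))`}
#'   \item{`monotone_spline`}{isotonic regression (direction chosen by the
#'     data) followed by a monotone Hermite spline through the fitted values}
#' }
#'
#' @param day Sampling days (>= 4 points).
#' @param value Observed values.
#' @param family One of `"exp_saturation"`, `"logistic"`, `"monotone_spline"`.
#' @return Object of class `recovery_fit`: `family`, `params` (named
#'   numeric; fitted ordinates for the spline), `rmse`, and `predict(t)`.
#' @export
fit_recovery_curve <- function(day, value,
                               family = c("exp_saturation", "logistic",
                                          "monotone_spline")) {
  family <- match.arg(family)
  keep <- is.finite(day) & is.finite(value)
  day <- day[keep]; value <- value[keep]
  if (length(day) < 4L) stop("need at least 4 points to fit a trend")
  o <- order(day); day <- day[o]; value <- value[o]

  if (family == "exp_saturation") {
    if (stats::sd(value) < 1e-10 * (abs(mean(value)) + 1)) {
      # constant data: the family degenerates to its asymptote (B = 0)
      A <- mean(value)
      params <- c(A = A, B = 0, tau = diff(range(day)))
      pred <- function(t) rep(A, length(t))
      return(structure(list(family = family, params = params,
                            rmse = sqrt(mean((value - A)^2)),
                            predict = pred, n = length(day)),
                       class = "recovery_fit"))
    }
    start <- list(A = max(value), B = max(value) - min(value) + 1e-8,
                  tau = diff(range(day)) / 3)
    fit <- tryCatch(
      minpack.lm::nlsLM(value ~ A - B * exp(-day / tau), start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 500,
                                                             ftol = 1e-14)),
      error = function(e) stop("exp_saturation fit failed on n = ",
                               length(day), " points: ", conditionMessage(e)))
    params <- stats::coef(fit)
    pred <- function(t) params[["A"]] - params[["B"]] * exp(-t / params[["tau"]])
  } else if (family == "logistic") {
    start <- list(A = max(value) * 1.05, t0 = stats::median(day),
                  s = diff(range(day)) / 6)
    fit <- tryCatch(
      minpack.lm::nlsLM(value ~ A / (1 + exp(-(day - t0) / s)), start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 500,
                                                             ftol = 1e-14)),
      error = function(e) stop("logistic fit failed on n = ",
                               length(day), " points: ", conditionMessage(e)))
    params <- stats::coef(fit)
    pred <- function(t) params[["A"]] / (1 + exp(-(t - params[["t0"]]) / params[["s"]]))
  } else {
    increasing <- stats::cor(day, value) >= 0
    iso <- if (increasing) stats::isoreg(day, value)
           else stats::isoreg(day, -value)
    yf <- if (increasing) iso$yf else -iso$yf
    ux <- unique(day)
    uy <- vapply(ux, function(d) mean(yf[day == d]), numeric(1))
    sp <- if (length(ux) >= 2L)
      stats::splinefun(ux, uy, method = "monoH.FC") else function(t) rep(uy, length(t))
    rng <- range(ux)
    pred <- function(t) sp(pmin(pmax(t, rng[1]), rng[2]))
    params <- stats::setNames(uy, paste0("f", ux))
  }
  structure(list(family = family, params = params,
                 rmse = sqrt(mean((pred(day) - value)^2)),
                 predict = pred, n = length(day)),
            class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf("Recovery fit (%s), n = %d, RMSE = %.4g\n", x$family, x$n, x$rmse))
  if (x$family != "monotone_spline")
    cat("  ", paste(names(x$params), signif(x$params, 6), sep = " = ",
                    collapse = ", "), "\n")
  invisible(x)
}

#' Linear regression of gait recovery on callus mineral density
#'
#' Ordinary least squares of the body-weight-normalized ground reaction
#' force on BMD at matched time-points, with a two-sided test of the slope.
#' Significance follows the study criterion: `R^2 > 0.5` and `p < 0.005`
#' (single regression; no multiplicity adjustment).
#'
#' @param grf GRF values, normalized by body weight (%BW by convention; a
#'   percent-of-healthy scale only rescales the slope).
#' @param bmd Bone mineral density (g HA/cm^3) at the same time-points.
#' @param r2_threshold,p_threshold Significance cutoffs. Defaults 0.5, 0.005.
#' @return Object of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`, `significant`.
#' @export
grf_bmd_regression <- function(grf, bmd, r2_threshold = 0.5,
                               p_threshold = 0.005) {
  keep <- is.finite(grf) & is.finite(bmd)
  grf <- grf[keep]; bmd <- bmd[keep]
  if (length(grf) < 3L) stop("need at least 3 paired observations")
  if (stats::var(bmd) == 0) stop("BMD has zero variance; regression undefined")
  fit <- stats::lm(grf ~ bmd)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  p <- sm$coefficients["bmd", "Pr(>|t|)"]
  r2 <- sm$r.squared
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, p_value = p, n = length(grf),
                 significant = r2 > r2_threshold && p < p_threshold),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "GRF ~ BMD: slope = %.4g, intercept = %.4g, R^2 = %.3f, p = %.3g, n = %d (%s)\n",
    x$slope, x$intercept, x$r_squared, x$p_value, x$n,
    if (x$significant) "significant" else "not significant"))
  invisible(x)
}
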