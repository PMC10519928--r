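# Gait processing: stance detection on walking-platform traces, per-tread
# peak extraction, and daily summaries normalized to healthy reference GRF.

GRAVITY <- 9.81 # m/s^2

#' Healthy peak ground reaction force for a hind limb
#'
#' In this ovine metatarsal model a healthy hind limb bears 42-43% of body
#' weight at amble; the midpoint 42.5% is the default reference.
#'
#' @param body_weight_kg Body weight (kg).
#' @param healthy_fraction Fraction of body weight borne by the healthy limb.
#' @return Reference peak GRF (N).
#' @export
healthy_grf <- function(body_weight_kg, healthy_fraction = 0.425) {
  stopifnot(body_weight_kg > 0, healthy_fraction > 0)
  healthy_fraction * body_weight_kg * GRAVITY
}

#' Detect stance phases in a force trace
#'
#' Finds maximal intervals where the platform force stays above a threshold,
#' with a hysteresis band to suppress chatter: a stance opens when the force
#' rises to `threshold` and closes when it falls below
#' `threshold - hysteresis`. Intervals shorter than `min_duration` are
#' dropped, except that an interval clipped by the end of the trace is kept
#' once the duration criterion is already met.
#'
#' @param t Sample times (s), uniformly spaced, increasing.
#' @param grf Baseline-corrected platform force (N), same length as `t`.
#' @param threshold Stance-on force (N); conventionally 5% of body weight.
#' @param hysteresis Width of the off-band (N); conventionally 1% of body
#'   weight.
#' @param min_duration Minimum stance duration (s). Default 0.2.
#' @return Data frame of disjoint, ordered intervals with columns
#'   `start`, `end` (sample indices), `t_start`, `t_end`, `duration`.
#' @export
detect_stance_phases <- function(t, grf, threshold, hysteresis = 0.2 * threshold,
                                 min_duration = 0.2) {
  stopifnot(length(t) == length(grf), threshold > 0, hysteresis >= 0)
  n <- length(t)
  empty <- data.frame(start = integer(), end = integer(),
                      t_start = numeric(), t_end = numeric(),
                      duration = numeric())
  if (n == 0L) return(empty)
  lo <- threshold - hysteresis
  starts <- integer(); ends <- integer()
  in_stance <- FALSE; s <- 0L
  for (i in seq_len(n)) {
    if (!in_stance && grf[i] >= threshold) {
      in_stance <- TRUE; s <- i
    } else if (in_stance && grf[i] < lo) {
      starts <- c(starts, s); ends <- c(ends, i - 1L)
      in_stance <- FALSE
    }
  }
  if (in_stance) { starts <- c(starts, s); ends <- c(ends, n) }
  if (!length(starts)) return(empty)
  out <- data.frame(start = starts, end = ends,
                    t_start = t[starts], t_end = t[ends])
  out$duration <- out$t_end - out$t_start
  out <- out[out$duration >= min_duration, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-tread peak forces
#'
#' For each detected stance interval, takes the maximum platform force and
#' the maximum fixator force over the same interval (peak-synchronized
#' pairing) as one tread observation.
#'
#' @param trace Data frame with columns `t`, `grf`, `ff` and (optionally)
#'   `day`; one recording session.
#' @param stances Stance intervals from [detect_stance_phases()].
#' @return Data frame with columns `day`, `tread`, `grf`, `ff`.
#' @export
peak_per_tread <- function(trace, stances) {
  stopifnot(all(c("t", "grf", "ff") %in% names(trace)))
  day <- if ("day" %in% names(trace)) trace$day[1] else NA_real_
  if (nrow(stances) == 0L)
    return(data.frame(day = numeric(), tread = integer(),
                      grf = numeric(), ff = numeric()))
  grf_pk <- mapply(function(s, e) max(trace$grf[s:e]), stances$start, stances$end)
  ff_pk  <- mapply(function(s, e) max(trace$ff[s:e]),  stances$start, stances$end)
  data.frame(day = day, tread = seq_len(nrow(stances)),
             grf = grf_pk, ff = ff_pk)
}

#' Daily gait summary
#'
#' Averages per-tread peaks within one day and expresses the mean peak GRF
#' as a percentage of the healthy reference. Days with fewer than
#' `min_treads` treads are kept but flagged incomplete.
#'
#' @param peaks Per-tread peaks for a single day (columns `day`, `grf`, `ff`).
#' @param body_weight_kg Body weight (kg).
#' @param healthy_fraction Healthy GRF as a fraction of body weight.
#' @param min_treads Minimum tread count for a complete session. Default 8.
#' @return One-row data frame: `day`, `n_treads`, `grf_N`, `ff_N`,
#'   `grf_pct`, `complete`.
#' @export
daily_summary <- function(peaks, body_weight_kg, healthy_fraction = 0.425,
                          min_treads = 8L) {
  if (nrow(peaks) == 0L) stop("no treads supplied")
  if (length(unique(peaks$day)) != 1L)
    stop("all peaks in a daily summary must share the same day")
  ref <- healthy_grf(body_weight_kg, healthy_fraction)
  data.frame(day = peaks$day[1],
             n_treads = nrow(peaks),
             grf_N = mean(peaks$grf),
             ff_N = mean(peaks$ff),
             grf_pct = 100 * mean(peaks$grf) / ref,
             complete = nrow(peaks) >= min_treads)
}

#' Extract per-tread peaks from a multi-day force-trace table
#'
#' Convenience wrapper: splits a long trace table by day, detects stances
#' with body-weight-scaled thresholds, and extracts peak pairs.
#'
#' @param traces Data frame in the trace dialect: columns `day`, `tread_id`
#'   (optional), `t`, `grf_N`, `ff_N`.
#' @param body_weight_kg Body weight (kg), used for the 5%/1% BW thresholds.
#' @param min_duration Minimum stance duration (s).
#' @return Data frame of per-tread peaks (columns `day`, `tread`, `grf`, `ff`).
#' @export
extract_tread_peaks <- function(traces, body_weight_kg, min_duration = 0.2) {
  stopifnot(all(c("day", "t", "grf_N", "ff_N") %in% names(traces)))
  bw_n <- body_weight_kg * GRAVITY
  thr <- 0.05 * bw_n
  hys <- 0.01 * bw_n
  out <- lapply(split(traces, traces$day), function(d) {
    tr <- data.frame(day = d$day, t = d$t, grf = d$grf_N, ff = d$ff_N)
    st <- detect_stance_phases(tr$t, tr$grf, threshold = thr, hysteresis = hys,
                               min_duration = min_duration)
    peak_per_tread(tr, st)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$day, out$tread), , drop = FALSE]
}

#' Read / write force traces in the trace CSV dialect
#'
#' Columns: `day` (float, days post-surgery), `tread_id` (int), `t` (s),
#' `grf_N`, `ff_N`. UTF-8, '.' decimal separator, one file per animal.
#'
#' @param path File path.
#' @return `read_force_trace` returns the trace data frame.
#' @export
read_force_trace <- function(path) {
  tr <- utils::read.csv(path)
  need <- c("day", "tread_id", "t", "grf_N", "ff_N")
  miss <- setdiff(need, names(tr))
  if (length(miss)) stop("trace file ", path, " lacks columns: ",
                         paste(miss, collapse = ", "))
  tr
}

#' @rdname read_force_trace
#' @param traces Trace data frame to write.
#' @export
write_force_trace <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE)
  invisible(path)
}
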