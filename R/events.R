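#' Per-trial event timeline
#'
#' Collects the five events that anchor every metric: reach onset and offset
#' (infrared sensor edges), net centre-of-pressure onset (first postural
#' deviation), step onset (landing-limb unloading) and step offset
#' (landing-zone contact). All times are seconds on the common trial clock
#' (time zero at the first sample, events snapped to samples of their source
#' stream).
#'
#' @param reach_on,reach_off,cop_on,step_on,step_off Event times in seconds
#'   (`NA` allowed for events not yet detected).
#' @param duration_s Trial duration; when supplied, events are checked to lie
#'   inside the trial.
#' @return An `event_set` list.
#' @export
event_set <- function(reach_on = NA_real_, reach_off = NA_real_,
                      cop_on = NA_real_, step_on = NA_real_,
                      step_off = NA_real_, duration_s = NULL) {
  ev <- list(reach_on = reach_on, reach_off = reach_off, cop_on = cop_on,
             step_on = step_on, step_off = step_off)
  fin <- function(a, b) is.finite(ev[[a]]) && is.finite(ev[[b]])
  if (fin("cop_on", "step_on") && ev$cop_on > ev$step_on)
    warning("cop_on follows step_on; trial kept but flagged", call. = FALSE)
  if (fin("step_on", "step_off") && ev$step_on >= ev$step_off)
    abort_data("step_on must precede step_off")
  if (fin("reach_on", "reach_off") && ev$reach_on >= ev$reach_off)
    abort_data("reach_on must precede reach_off")
  if (!is.null(duration_s)) {
    v <- unlist(ev)
    if (any(v[is.finite(v)] < 0) || any(v[is.finite(v)] > duration_s))
      abort_data("events must lie within [0, duration_s]")
  }
  structure(ev, class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  cat("<event_set>\n")
  for (nm in names(x)) cat(sprintf("  %-9s %s\n", nm,
                                   ifelse(is.finite(x[[nm]]),
                                          sprintf("%.3f s", x[[nm]]), "NA")))
  invisible(x)
}

#' Detect reach onset and offset from the infrared beam channel
#'
#' The beam channel is 1 while the hand is in transit: reach onset is the
#' first rising edge (hand departure), reach offset the next falling edge
#' (target contact).
#'
#' @param sensor Binary (0/1) numeric vector.
#' @param rate Sensor sampling rate in Hz.
#' @return `c(reach_on, reach_off)` in seconds.
#' @export
detect_reach_events <- function(sensor, rate) {
  check_scalar_number(rate, "rate", positive = TRUE)
  if (!all(sensor %in% c(0, 1)))
    abort_data("sensor stream must be binary 0/1")
  d <- diff(sensor)
  rise <- which(d == 1)
  if (!length(rise))
    abort_data("unanalyzable trial: no hand-departure edge in sensor stream")
  on_idx <- rise[1] + 1L
  fall <- which(d == -1)
  fall <- fall[fall + 1L > on_idx]
  if (!length(fall))
    abort_data("unanalyzable trial: no target-contact edge after reach onset")
  off_idx <- fall[1] + 1L
  c(reach_on = (on_idx - 1L) / rate, reach_off = (off_idx - 1L) / rate)
}

#' Detect the onset of the net centre-of-pressure shift
#'
#' Scans the AP and ML components of the net CoP for the first excursion
#' beyond `baseline mean +/- k_sd * baseline SD` sustained for `sustain_s`,
#' taking whichever axis deviates first. With `refine = "extrapolate"`
#' (default) the threshold crossing is then refined by fitting a line to the
#' `refine_s` seconds following the crossing and extrapolating back to the
#' baseline mean, which removes the threshold-crossing bias and is exact for
#' ramp-like shifts at zero noise; `refine = "none"` reports the raw sustained
#' crossing.
#'
#' @param cop Matrix or data frame with columns `ap` and `ml` (metres), net
#'   CoP on the force-plate clock.
#' @param rate Sampling rate in Hz.
#' @param baseline_window `c(start_s, end_s)` quiet-stance window (>= 0.5 s).
#' @param k_sd Threshold multiplier (default 3).
#' @param sustain_s Sustain requirement in seconds (default 0.025).
#' @param refine `"extrapolate"` (default) or `"none"`.
#' @param refine_s Length of the post-crossing fit segment (default 0.05).
#' @param min_dev Absolute floor on the deviation threshold in metres
#'   (default 1e-6): keeps a near-noiseless baseline from firing on
#'   floating-point residue.
#' @param lp_hz Optional zero-phase low-pass cutoff (Hz) applied to both CoP
#'   axes before detection — the usual posturographic pre-smoothing for noisy
#'   plates. `NULL` (default) detects on the stream as given.
#' @return Onset time in seconds (sample-aligned), or `NA_real_` with a
#'   warning when no deviation is found.
#' @export
detect_cop_onset <- function(cop, rate, baseline_window = c(0, 0.5),
                             k_sd = 3, sustain_s = 0.025,
                             refine = c("extrapolate", "none"),
                             refine_s = 0.05, min_dev = 1e-6, lp_hz = NULL) {
  refine <- match.arg(refine)
  cop <- as.data.frame(cop)
  if (!all(c("ap", "ml") %in% names(cop)))
    abort_data("net CoP must provide `ap` and `ml` columns")
  if (diff(baseline_window) < 0.5)
    abort_config("CoP baseline window must be at least 0.5 s long")
  if (!is.null(lp_hz)) {
    bw <- signal::butter(2, lp_hz / (rate / 2), type = "low")
    cop$ap <- zero_phase(cop$ap, bw$b, bw$a, rate)
    cop$ml <- zero_phase(cop$ml, bw$b, bw$a, rate)
  }
  onset_axis <- function(x) {
    i0 <- floor(baseline_window[1] * rate) + 1L
    i1 <- min(length(x), ceiling(baseline_window[2] * rate))
    mu <- mean(x[i0:i1]); s <- sd(x[i0:i1])
    dev <- abs(x - mu) > max(k_sd * s, min_dev)
    n_sus <- max(1L, round(sustain_s * rate))
    r <- rle(dev)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    ok <- which(r$values & r$lengths >= n_sus)
    if (!length(ok)) return(NA_integer_)
    cross <- starts[ok[1]]
    if (refine == "none") return(cross)
    seg <- cross:min(length(x), cross + max(2L, round(refine_s * rate)))
    fit <- lm(y ~ t, data = data.frame(t = seg, y = x[seg]))
    b <- coef(fit)
    if (!is.finite(b[2]) || b[2] == 0) return(cross)
    t0 <- (mu - b[1]) / b[2]
    idx <- round(t0)
    if (!is.finite(idx)) return(cross)
    max(1L, min(cross, idx))
  }
  idx_ap <- onset_axis(cop$ap)
  idx_ml <- onset_axis(cop$ml)
  if (is.na(idx_ap) && is.na(idx_ml)) {
    warning("no CoP deviation found; trial flagged", call. = FALSE)
    return(NA_real_)
  }
  (min(idx_ap, idx_ml, na.rm = TRUE) - 1L) / rate
}

#' Detect step onset and offset from landing-limb vertical force
#'
#' Step onset is the first time the landing-limb vertical ground reaction
#' force drops below `unload_frac` (default 5%) of its quiet-stance value;
#' step offset is the first subsequent time the landing-zone vertical load
#' rises above `load_frac` (default 5%) of body weight.
#'
#' @param fz_landing Vertical force of the landing limb / landing zone (N),
#'   on the force-plate clock.
#' @param rate Sampling rate in Hz.
#' @param body_weight Body weight in newtons.
#' @param baseline_window `c(start_s, end_s)` quiet-stance window.
#' @param unload_frac,load_frac Threshold fractions (defaults 0.05).
#' @return `c(step_on, step_off)` in seconds.
#' @export
detect_step_events <- function(fz_landing, rate, body_weight,
                               baseline_window = c(0, 0.5),
                               unload_frac = 0.05, load_frac = 0.05) {
  check_scalar_number(body_weight, "body_weight", positive = TRUE)
  i0 <- floor(baseline_window[1] * rate) + 1L
  i1 <- min(length(fz_landing), ceiling(baseline_window[2] * rate))
  quiet <- mean(fz_landing[i0:i1])
  if (quiet <= 0) abort_data("landing limb is unloaded during quiet stance")
  on_idx <- which(fz_landing < unload_frac * quiet)
  on_idx <- on_idx[on_idx > i1]
  if (!length(on_idx))
    abort_data("unanalyzable trial: landing limb never unloads")
  on_idx <- on_idx[1]
  off_idx <- which(fz_landing > load_frac * body_weight)
  off_idx <- off_idx[off_idx > on_idx]
  if (!length(off_idx))
    abort_data("unanalyzable trial: no landing-zone contact after step onset")
  c(step_on = (on_idx - 1L) / rate, step_off = (off_idx[1] - 1L) / rate)
}

#' Step length, width and time from malleoli trajectories
#'
#' Step length is the AP distance and step width the ML distance between the
#' support- and landing-limb malleoli, both evaluated at step offset (foot
#' flat at landing); step time is `step_off - step_on`.
#'
#' @param malleoli Data frame with columns `time`, `support_ap`, `support_ml`,
#'   `landing_ap`, `landing_ml` (metres, kinematic clock).
#' @param events An [event_set()] with finite `step_on` and `step_off`.
#' @return A tibble with `step_length`, `step_width`, `step_time`.
#' @export
compute_step_characteristics <- function(malleoli, events) {
  need <- c("time", "support_ap", "support_ml", "landing_ap", "landing_ml")
  missing_cols <- setdiff(need, names(malleoli))
  if (length(missing_cols))
    abort_data(paste0("malleoli trajectories missing column(s): ",
                      paste(missing_cols, collapse = ", ")))
  if (!is.finite(events$step_on) || !is.finite(events$step_off))
    abort_data("step events required for step characteristics")
  if (max(malleoli$time) < events$step_off)
    abort_data("kinematic stream ends before step offset")
  at <- function(col) {
    stats::approx(malleoli$time, malleoli[[col]], xout = events$step_off,
                  rule = 2)$y
  }
  tibble::tibble(
    step_length = abs(at("landing_ap") - at("support_ap")),
    step_width = abs(at("landing_ml") - at("support_ml")),
    step_time = events$step_off - events$step_on
  )
}
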