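#' Preparatory centre-of-mass metrics
#'
#' Computed on the preparatory interval `[cop_on, step_on]`: per-axis CoM
#' excursion (max - min of position) and peak CoM acceleration (magnitude of
#' the extreme second derivative). The second derivative is estimated with a
#' Savitzky-Golay differentiating filter over the full stream (window
#' `sg_window`, order `sg_polyorder`), which suppresses the noise
#' amplification that plain double differencing of a sampled position
#' exhibits; signs of the peak accelerations are retained in separate
#' columns.
#'
#' @param com Data frame with columns `time`, `ap`, `ml` (metres; smoothed
#'   CoM position on the kinematic clock).
#' @param events An [event_set()] with finite `cop_on` and `step_on`.
#' @param sg_window,sg_polyorder Savitzky-Golay settings for the
#'   differentiating filter (defaults 41 samples, order 3; an even window is
#'   rounded up to odd).
#' @return A tibble with `prep_com_acc_ap`, `prep_com_acc_ml` (m/s^2,
#'   magnitudes), `prep_acc_sign_ap`, `prep_acc_sign_ml`, `prep_com_exc_ap`,
#'   `prep_com_exc_ml` (m). All-`NA` row (with a warning) when the interval
#'   holds fewer than 3 samples.
#' @export
preparatory_com_metrics <- function(com, events, sg_window = 41,
                                    sg_polyorder = 3) {
  if (!all(c("time", "ap", "ml") %in% names(com)))
    abort_data("CoM stream must provide `time`, `ap`, `ml` columns")
  if (!is.finite(events$cop_on) || !is.finite(events$step_on) ||
      events$cop_on >= events$step_on)
    abort_data("preparatory interval requires cop_on < step_on")
  idx <- which(com$time >= events$cop_on - 1e-9 & com$time <= events$step_on + 1e-9)
  if (length(idx) < 3L) {
    warning("preparatory interval shorter than 3 kinematic samples; metrics missing",
            call. = FALSE)
    return(tibble::tibble(prep_com_acc_ap = NA_real_, prep_com_acc_ml = NA_real_,
                          prep_acc_sign_ap = NA_real_, prep_acc_sign_ml = NA_real_,
                          prep_com_exc_ap = NA_real_, prep_com_exc_ml = NA_real_))
  }
  dt <- stats::median(diff(com$time))
  n <- length(com$ap)
  w <- min(as.integer(sg_window), if (n %% 2L == 0L) n - 1L else n)
  if (w %% 2L == 0L) w <- w + 1L
  wmin <- as.integer(sg_polyorder) + 2L
  if (wmin %% 2L == 0L) wmin <- wmin + 1L
  w <- max(w, wmin)
  peak_acc <- function(x) {
    acc <- signal::sgolayfilt(x, p = sg_polyorder, n = w, m = 2, ts = dt)
    acc <- acc[idx]
    acc[which.max(abs(acc))]
  }
  a_ap <- peak_acc(com$ap); a_ml <- peak_acc(com$ml)
  tibble::tibble(
    prep_com_acc_ap = abs(a_ap), prep_com_acc_ml = abs(a_ml),
    prep_acc_sign_ap = sign(a_ap), prep_acc_sign_ml = sign(a_ml),
    prep_com_exc_ap = diff(range(com$ap[idx])),
    prep_com_exc_ml = diff(range(com$ml[idx]))
  )
}

#' Total centre-of-mass excursion across the movement
#'
#' Peak-to-peak CoM displacement per axis over the movement interval, taken
#' here as `[cop_on, reach_off]` (postural preparation through target
#' contact); both endpoints are configurable through `interval`.
#'
#' @param com Data frame with `time`, `ap`, `ml` columns.
#' @param events An [event_set()].
#' @param interval Optional `c(start_s, end_s)` override of the movement
#'   interval.
#' @return A tibble with `total_com_exc_ap`, `total_com_exc_ml` (m).
#' @export
total_com_excursion <- function(com, events, interval = NULL) {
  if (is.null(interval)) {
    if (!is.finite(events$cop_on) || !is.finite(events$reach_off))
      abort_data("movement interval requires cop_on and reach_off")
    interval <- c(events$cop_on, events$reach_off)
  }
  idx <- which(com$time >= interval[1] - 1e-9 & com$time <= interval[2] + 1e-9)
  if (!length(idx)) abort_data("movement interval contains no kinematic samples")
  tibble::tibble(
    total_com_exc_ap = diff(range(com$ap[idx])),
    total_com_exc_ml = diff(range(com$ml[idx]))
  )
}

#' Peak-to-peak joint excursions over the movement
#'
#' @param joints Data frame with a `time` column and one column per joint
#'   angle in degrees (ankle, knee, hip, lumbar, thorax, shoulder, elbow by
#'   default; any subset is accepted, missing joints yield `NA` with a
#'   warning).
#' @param events An [event_set()].
#' @param joint_names Joints to report.
#' @param interval Optional movement-interval override (default
#'   `[cop_on, reach_off]`).
#' @return A tibble with one `exc_<joint>` column per joint (degrees).
#' @export
peak_joint_excursions <- function(joints, events,
                                  joint_names = c("ankle", "knee", "hip",
                                                  "lumbar", "thorax",
                                                  "shoulder", "elbow"),
                                  interval = NULL) {
  if (is.null(interval)) {
    if (!is.finite(events$cop_on) || !is.finite(events$reach_off))
      abort_data("movement interval requires cop_on and reach_off")
    interval <- c(events$cop_on, events$reach_off)
  }
  idx <- which(joints$time >= interval[1] - 1e-9 & joints$time <= interval[2] + 1e-9)
  if (!length(idx)) abort_data("movement interval contains no kinematic samples")
  vals <- lapply(joint_names, function(j) {
    if (!j %in% names(joints)) {
      warning(sprintf("joint '%s' missing from kinematic stream", j),
              call. = FALSE)
      return(NA_real_)
    }
    diff(range(joints[[j]][idx]))
  })
  names(vals) <- paste0("exc_", joint_names)
  tibble::as_tibble(vals)
}

#' All movement metrics for one conditioned trial
#'
#' Convenience wrapper combining [compute_step_characteristics()],
#' [preparatory_com_metrics()], [total_com_excursion()] and
#' [peak_joint_excursions()] into the single-row per-trial record consumed by
#' the cohort table.
#'
#' @param kin Conditioned kinematic data frame (columns `time`, `com_ap`,
#'   `com_ml`, joint angles, malleoli columns).
#' @param events An [event_set()].
#' @return A one-row tibble of movement metrics.
#' @export
trial_movement_metrics <- function(kin, events) {
  com <- data.frame(time = kin$time, ap = kin$com_ap, ml = kin$com_ml)
  mal <- kin[, c("time", "support_ap", "support_ml", "landing_ap", "landing_ml")]
  dplyr::bind_cols(
    compute_step_characteristics(mal, events),
    preparatory_com_metrics(com, events),
    total_com_excursion(com, events),
    peak_joint_excursions(kin, events)
  )
}
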