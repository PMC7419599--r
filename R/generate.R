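# Synthetic step-and-reach cohort generator.
#
# Every trial is built from a small set of continuous-time constructions
# (logistic unloading, ramped CoP shift, piecewise half-cosine CoM paths,
# ramped EMG burst envelopes) whose parameters ARE the ground truth, so the
# detector and metric modules can be validated against exactly known values.

snap_time <- function(t, rate) round(t * rate) / rate

time_grid <- function(duration_s, rate) seq(0, by = 1 / rate,
                                            length.out = round(duration_s * rate))

half_cos_rise <- function(t, t0, t1) {
  # 0 before t0, 1 after t1, smooth half-cosine in between
  u <- pmin(1, pmax(0, (t - t0) / max(t1 - t0, .Machine$double.eps)))
  (1 - cos(pi * u)) / 2
}

raised_cos_bump <- function(t, t0, t1) {
  u <- (t - t0) / max(t1 - t0, .Machine$double.eps)
  ifelse(u >= 0 & u <= 1, (1 - cos(2 * pi * u)) / 2, 0)
}

linear_ramp <- function(t, t0, t1) pmin(1, pmax(0, (t - t0) / max(t1 - t0, 1e-12)))

#' Generate one synthetic raw EMG channel
#'
#' The baseline is zero-mean Gaussian noise of SD `baseline_sd` plus a small
#' 60 Hz mains component (half the baseline SD; removed downstream by the
#' notch). Each burst adds an activation `envelope(t) * z(t)` with `z`
#' standard Gaussian noise, where the envelope rises from 0 to the stated
#' peak amplitude over a 10 ms half-cosine ramp, holds, and falls over a
#' 10 ms ramp; the ground-truth onset is the ramp start. Bursts may overlap
#' (envelopes add).
#'
#' @param duration_s Signal length in seconds.
#' @param rate Sampling rate in Hz.
#' @param baseline_sd Baseline noise SD (>= 0).
#' @param bursts Data frame with columns `onset_s`, `duration_s`,
#'   `amplitude`; may have zero rows.
#' @param seed Integer seed (the channel is deterministic given it).
#' @param ramp_s Envelope rise/fall time (default 0.010 s).
#' @param mains_hz,mains_frac Mains interference frequency and amplitude as a
#'   fraction of `baseline_sd`.
#' @return Numeric vector of `duration_s * rate` samples.
#' @export
generate_emg_channel <- function(duration_s, rate, baseline_sd, bursts = NULL,
                                 seed = 1, ramp_s = 0.010, mains_hz = 60,
                                 mains_frac = 0.5) {
  check_scalar_number(duration_s, "duration_s", positive = TRUE)
  check_scalar_number(rate, "rate", positive = TRUE)
  if (baseline_sd < 0) abort_config("`baseline_sd` must be >= 0")
  t <- time_grid(duration_s, rate)
  env <- numeric(length(t))
  if (!is.null(bursts) && nrow(as.data.frame(bursts))) {
    bursts <- as.data.frame(bursts)
    if (any(bursts$amplitude < 0))
      abort_config("burst amplitudes must be >= 0")
    if (any(bursts$onset_s < 0 | bursts$onset_s + bursts$duration_s > duration_s))
      abort_config("bursts must lie within [0, duration_s]")
    for (i in seq_len(nrow(bursts))) {
      on <- bursts$onset_s[i]; dur <- bursts$duration_s[i]
      r <- min(ramp_s, dur / 2)
      env <- env + bursts$amplitude[i] *
        (half_cos_rise(t, on, on + r) - half_cos_rise(t, on + dur - r, on + dur))
    }
  }
  with_seed(seed, {
    x <- stats::rnorm(length(t), 0, baseline_sd) +
      mains_frac * baseline_sd * sin(2 * pi * mains_hz * t)
    x + env * stats::rnorm(length(t))
  })
}

# Realize one trial's latent parameters (metric values, event times, muscle
# onsets, VAS) from the effect/noise model. All randomness comes from
# counter-derived streams of the master seed.
realize_trial_params <- function(spec, group_i, part_i, cond_i, trial_i) {
  eff <- spec$effects
  group <- spec$groups[group_i]
  cond <- spec$conditions[cond_i]
  metric_names <- names(eff)

  subj <- with_seed(derive_seed(spec$seed, 1, group_i, part_i), {
    setNames(vapply(metric_names,
                    function(m) stats::rnorm(1, 0, eff[[m]]$subject_sd),
                    numeric(1)), metric_names)
  })
  draws <- with_seed(derive_seed(spec$seed, 2, group_i, part_i, cond_i, trial_i), {
    eps <- setNames(vapply(metric_names,
                           function(m) stats::rnorm(1, 0, eff[[m]]$trial_sd),
                           numeric(1)), metric_names)
    jit <- stats::rnorm(16, 0, 0.010)
    list(eps = eps, onset_jitter = jit)
  })
  vas_eps <- with_seed(derive_seed(spec$seed, 3, group_i, part_i, cond_i), {
    c(likely = stats::rnorm(1, 0, eff$vas_likely$trial_sd),
      concern = stats::rnorm(1, 0, eff$vas_concern$trial_sd))
  })

  val <- function(m, eps = draws$eps[[m]]) {
    e <- eff[[m]]
    v <- e$base
    if (cond %in% names(e$cond)) v <- v + e$cond[[cond]]
    if (group %in% names(e$group_d)) v <- v + e$group_d[[group]]
    if (!is.null(e$inter[[group]]) && cond %in% names(e$inter[[group]]))
      v <- v + e$inter[[group]][[cond]]
    v + subj[[m]] + eps
  }

  fr <- spec$rates$force
  cop_on <- snap_time(max(1.0, val("cop_on")), fr)
  step_on <- snap_time(cop_on + max(0.1, val("prep_duration")), fr)
  step_time <- max(0.1, val("step_time"))
  step_off <- snap_time(step_on + step_time, fr)
  reach_on <- snap_time(step_on + val("reach_delay"), fr)
  reach_off <- snap_time(max(step_off + 0.05, reach_on + max(0.3, val("reach_duration"))),
                         fr)
  if (reach_off > spec$duration_s - 0.1)
    abort_config("trial too short for the configured event timeline")
  events <- event_set(reach_on = reach_on, reach_off = reach_off,
                      cop_on = cop_on, step_on = step_on, step_off = step_off,
                      duration_s = spec$duration_s)

  metrics <- list(
    step_length = max(0, val("step_length")),
    step_width = max(0, val("step_width")),
    step_time = step_off - step_on,
    prep_com_exc_ap = max(0, val("prep_com_exc_ap")),
    prep_com_exc_ml = max(0, val("prep_com_exc_ml")),
    total_com_exc_ap = max(0, val("total_com_exc_ap")),
    total_com_exc_ml = max(0, val("total_com_exc_ml"))
  )
  # the CoM path never exceeds its total excursion during preparation
  metrics$total_com_exc_ap <- max(metrics$total_com_exc_ap, metrics$prep_com_exc_ap)
  metrics$total_com_exc_ml <- max(metrics$total_com_exc_ml, metrics$prep_com_exc_ml)
  for (j in c("ankle", "knee", "hip", "lumbar", "thorax", "shoulder", "elbow"))
    metrics[[paste0("exc_", j)]] <- max(0, val(paste0("exc_", j)))
  Tprep <- step_on - cop_on
  metrics$prep_com_acc_ap <- metrics$prep_com_exc_ap * (pi / Tprep)^2 / 2
  metrics$prep_com_acc_ml <- metrics$prep_com_exc_ml * (pi / Tprep)^2 / 2

  # Muscle onsets relative to reach onset: trunk extensors and tibialis
  # anterior are preparatory in everyone; rectus abdominis and gastrocnemius
  # precede the reach in YOUNG but follow it in OLDER participants.
  base_lat <- c(ES = -0.12, TA = -0.10, VL = 0.03, BF = 0.03, AD = 0.02, BB = 0.02)
  ra_ga <- if (group == "OLDER") 0.08 else -0.05
  chans <- emg_channels()
  lat <- vapply(chans, function(ch) {
    mus <- sub("_[LR]$", "", ch)
    if (mus %in% c("RA", "GA")) ra_ga else base_lat[[mus]]
  }, numeric(1))
  onsets <- snap_time(reach_on + lat + draws$onset_jitter, spec$rates$emg)
  names(onsets) <- chans

  vas <- c(
    likely = min(100, max(0, val("vas_likely", eps = 0) + vas_eps[["likely"]])),
    concern = min(100, max(0, val("vas_concern", eps = 0) + vas_eps[["concern"]]))
  )
  list(events = events, metrics = metrics, onsets = onsets, vas = vas,
       group = group, condition = cond)
}

build_emg <- function(spec, params, group_i, part_i, cond_i, trial_i) {
  noise <- spec$noise
  sd0 <- noise$emg_baseline_sd
  amp <- noise$emg_burst_snr * if (sd0 > 0) sd0 else 0.02
  t <- time_grid(spec$duration_s, spec$rates$emg)
  out <- list(time = t)
  chans <- emg_channels()
  for (i in seq_along(chans)) {
    on <- params$onsets[[chans[i]]]
    dur <- min(0.5, spec$duration_s - on - 1 / spec$rates$emg)
    out[[chans[i]]] <- generate_emg_channel(
      spec$duration_s, spec$rates$emg, sd0,
      bursts = data.frame(onset_s = on, duration_s = dur, amplitude = amp),
      seed = derive_seed(spec$seed, 4, group_i, part_i, cond_i, trial_i, i))
  }
  tibble::as_tibble(out)
}

build_force <- function(spec, params, group_i, part_i, cond_i, trial_i) {
  ev <- params$events
  m <- params$metrics
  rate <- spec$rates$force
  t <- time_grid(spec$duration_s, rate)
  bw <- spec$body_mass_kg * 9.81
  f0 <- bw / 2

  s_un <- 0.015                       # ~90 ms 5-95% unloading width
  tc_on <- ev$step_on - s_un * log(19)
  fz_unload <- f0 * (1 - stats::plogis((t - tc_on) / s_un))
  s_re <- 0.010
  tc_off <- ev$step_off + s_re * log(7)
  fz_reload <- 0.4 * bw * stats::plogis((t - tc_off) / s_re)
  fz_landing <- fz_unload + fz_reload
  fz_support <- bw - fz_landing

  # anticipatory CoP shift: ML deviates first (toward the stepping limb),
  # AP follows 50 ms later; both linear ramps starting at cop_on
  shift_ml <- 0.03 * linear_ramp(t, ev$cop_on, ev$cop_on + 0.15)
  shift_ap <- 0.02 * linear_ramp(t, ev$cop_on + 0.05, ev$cop_on + 0.20)

  noise <- spec$noise
  with_seed(derive_seed(spec$seed, 5, group_i, part_i, cond_i, trial_i), {
    n <- length(t)
    cop1_ap <- shift_ap + stats::rnorm(n, 0, noise$cop_sd)
    cop1_ml <- -0.10 + shift_ml + stats::rnorm(n, 0, noise$cop_sd)
    land_ml_final <- -0.10 + m$step_width
    settle <- ev$step_on + 0.5 * (ev$step_off - ev$step_on)
    prog <- half_cos_rise(t, ev$step_on, settle)
    cop2_ap <- shift_ap * (1 - prog) + m$step_length * prog +
      stats::rnorm(n, 0, noise$cop_sd)
    cop2_ml <- (0.10 + shift_ml) * (1 - prog) + land_ml_final * prog +
      stats::rnorm(n, 0, noise$cop_sd)
    fz1 <- pmax(0, fz_support + stats::rnorm(n, 0, noise$force_sd))
    fz2 <- pmax(0, fz_landing + stats::rnorm(n, 0, noise$force_sd))
    tibble::tibble(
      time = t,
      p1_fx = stats::rnorm(n, 0, noise$force_sd),
      p1_fy = stats::rnorm(n, 0, noise$force_sd),
      p1_fz = fz1,
      p1_mx = cop1_ml * fz1, p1_my = -cop1_ap * fz1,
      p1_mz = stats::rnorm(n, 0, noise$force_sd * 0.1),
      p2_fx = stats::rnorm(n, 0, noise$force_sd),
      p2_fy = stats::rnorm(n, 0, noise$force_sd),
      p2_fz = fz2,
      p2_mx = cop2_ml * fz2, p2_my = -cop2_ap * fz2,
      p2_mz = stats::rnorm(n, 0, noise$force_sd * 0.1)
    )
  })
}

build_kin <- function(spec, params, group_i, part_i, cond_i, trial_i) {
  ev <- params$events
  m <- params$metrics
  rate <- spec$rates$kin
  t <- time_grid(spec$duration_s, rate)
  prep <- half_cos_rise(t, ev$cop_on, ev$step_on)
  move <- half_cos_rise(t, ev$step_on, ev$reach_off)
  com_ap <- m$prep_com_exc_ap * prep + (m$total_com_exc_ap - m$prep_com_exc_ap) * move
  com_ml <- m$prep_com_exc_ml * prep + (m$total_com_exc_ml - m$prep_com_exc_ml) * move

  joints <- list(ankle = 10, knee = 20, hip = 15, lumbar = 5, thorax = 5,
                 shoulder = 10, elbow = 20)
  bump <- raised_cos_bump(t, ev$cop_on, ev$reach_off)
  # the swing foot decelerates and is essentially flat slightly before contact
  settle <- ev$step_on + 0.5 * (ev$step_off - ev$step_on)
  step_prog <- half_cos_rise(t, ev$step_on, settle)

  noise <- spec$noise
  with_seed(derive_seed(spec$seed, 6, group_i, part_i, cond_i, trial_i), {
    n <- length(t)
    out <- list(
      time = t,
      com_ap = com_ap + stats::rnorm(n, 0, noise$kin_sd),
      com_ml = com_ml + stats::rnorm(n, 0, noise$kin_sd),
      com_z = 0.97 + stats::rnorm(n, 0, noise$kin_sd)
    )
    for (j in names(joints)) {
      out[[j]] <- joints[[j]] + m[[paste0("exc_", j)]] * bump +
        stats::rnorm(n, 0, noise$angle_sd)
    }
    out$support_ap <- stats::rnorm(n, 0, noise$kin_sd)
    out$support_ml <- -0.10 + stats::rnorm(n, 0, noise$kin_sd)
    out$landing_ap <- m$step_length * step_prog + stats::rnorm(n, 0, noise$kin_sd)
    out$landing_ml <- 0.10 + (m$step_width - 0.20) * step_prog +
      stats::rnorm(n, 0, noise$kin_sd)
    tibble::as_tibble(out)
  })
}

build_sensor <- function(spec, params) {
  rate <- spec$rates$force
  t <- time_grid(spec$duration_s, rate)
  tibble::tibble(
    time = t,
    state = as.numeric(t >= params$events$reach_on - 1e-9 &
                         t < params$events$reach_off - 1e-9)
  )
}

#' Generate one synthetic step-and-reach trial with ground truth
#'
#' @param spec A [cohort_spec()].
#' @param group_i,part_i,cond_i,trial_i 1-based indices into the spec's
#'   groups, participants-within-group, conditions and trials.
#' @return List with `recording` (fields `emg`, `force`, `kin`, `sensor`,
#'   `meta`) and `truth` (fields `events`, `metrics`, `muscle_onsets`,
#'   `vas`).
#' @export
generate_trial <- function(spec, group_i, part_i, cond_i, trial_i) {
  params <- realize_trial_params(spec, group_i, part_i, cond_i, trial_i)
  participant <- sprintf("%s%02d", substr(spec$groups[group_i], 1, 1), part_i)
  meta <- list(
    participant = participant, group = params$group,
    condition = params$condition, trial = trial_i,
    vas_likely = unname(params$vas[["likely"]]),
    vas_concern = unname(params$vas[["concern"]]),
    body_mass_kg = spec$body_mass_kg, duration_s = spec$duration_s,
    rates = spec$rates
  )
  recording <- structure(
    list(emg = build_emg(spec, params, group_i, part_i, cond_i, trial_i),
         force = build_force(spec, params, group_i, part_i, cond_i, trial_i),
         kin = build_kin(spec, params, group_i, part_i, cond_i, trial_i),
         sensor = build_sensor(spec, params),
         meta = meta),
    class = "trial_recording")
  truth <- list(events = params$events, metrics = params$metrics,
                muscle_onsets = params$onsets, vas = params$vas)
  list(recording = recording, truth = truth)
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> %s %s/%s trial %d: %d EMG / %d force / %d kin samples\n",
              x$meta$participant, x$meta$group, x$meta$condition, x$meta$trial,
              nrow(x$emg), nrow(x$force), nrow(x$kin)))
  invisible(x)
}

#' The trial design table of a cohort specification
#'
#' @param spec A [cohort_spec()].
#' @return Tibble with one row per trial: `participant`, `group`,
#'   `condition`, `trial` and the generator indices.
#' @export
cohort_design <- function(spec) {
  d <- expand.grid(trial_i = seq_len(spec$trials_per_condition),
                   cond_i = seq_along(spec$conditions),
                   part_i = seq_len(spec$n_per_group),
                   group_i = seq_along(spec$groups))
  d <- d[order(d$group_i, d$part_i, d$cond_i, d$trial_i), ]
  tibble::tibble(
    participant = sprintf("%s%02d", substr(spec$groups[d$group_i], 1, 1), d$part_i),
    group = spec$groups[d$group_i],
    condition = spec$conditions[d$cond_i],
    trial = d$trial_i,
    group_i = d$group_i, part_i = d$part_i, cond_i = d$cond_i, trial_i = d$trial_i
  )
}

#' Generate a full synthetic cohort
#'
#' Deterministic given the spec's seed; trials are independent streams of a
#' counter-expanded master seed, so regenerating any single trial yields
#' bit-identical channels.
#'
#' @param spec A [cohort_spec()].
#' @return A list of `list(recording, truth)` pairs in blocked design order,
#'   with the design table attached as attribute `"design"`.
#' @export
generate_cohort <- function(spec) {
  design <- cohort_design(spec)
  trials <- lapply(seq_len(nrow(design)), function(i) {
    generate_trial(spec, design$group_i[i], design$part_i[i],
                   design$cond_i[i], design$trial_i[i])
  })
  attr(trials, "design") <- design
  trials
}

#' Force-plate and kinematic streams for one condition/group cell
#'
#' Convenience wrapper exposing the force/kinematics construction in
#' isolation (participant 1, trial 1 of the requested cell).
#'
#' @param condition,group Labels drawn from the spec.
#' @param spec A [cohort_spec()].
#' @return List with `force`, `kin`, `sensor` streams and `truth`.
#' @export
generate_force_and_kinematics <- function(condition, group, spec = cohort_spec()) {
  gi <- match(group, spec$groups)
  ci <- match(condition, spec$conditions)
  if (is.na(gi)) abort_config(sprintf("unknown group '%s'", group))
  if (is.na(ci)) abort_config(sprintf("unknown condition '%s'", condition))
  params <- realize_trial_params(spec, gi, 1L, ci, 1L)
  list(force = build_force(spec, params, gi, 1L, ci, 1L),
       kin = build_kin(spec, params, gi, 1L, ci, 1L),
       sensor = build_sensor(spec, params),
       truth = list(events = params$events, metrics = params$metrics))
}

#' Net centre of pressure from the dual-plate force table
#'
#' Global-frame CoP from the vertical forces and plate moments:
#' `ap = -(p1_my + p2_my) / (p1_fz + p2_fz)`,
#' `ml = (p1_mx + p2_mx) / (p1_fz + p2_fz)`.
#'
#' @param force Force table as produced by the generator / trial bundle.
#' @return Tibble with `time`, `ap`, `ml`.
#' @export
net_cop <- function(force) {
  fz <- force$p1_fz + force$p2_fz
  fz[fz <= 0] <- NA_real_
  tibble::tibble(
    time = force$time,
    ap = -(force$p1_my + force$p2_my) / fz,
    ml = (force$p1_mx + force$p2_mx) / fz
  )
}
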