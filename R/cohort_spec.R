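#' Per-metric effect configuration for the synthetic cohort
#'
#' Each entry defines the generative model of one metric:
#' `value(group, condition) = base + cond[condition] + group_d[group] +
#' inter[[group]][condition] + N(0, subject_sd) per participant +
#' N(0, trial_sd) per trial`. The defaults encode the study conditions the
#' generator emulates: a monotone rise of both fear VAS scales across the
#' blocked conditions, wider (and slightly shorter) steps under the
#' most-threatening surface, increased lumbar and thoracic flexion with
#' reduced support-limb ankle excursion, and a group x condition interaction
#' on total ML CoM excursion (young participants increase it under threat,
#' older participants reduce it).
#'
#' @param ... Named overrides; each value is a list that replaces (by field)
#'   the default entry of the same name.
#' @return Named list of metric entries, class `effect_config`.
#' @export
effect_config <- function(...) {
  entry <- function(base, cond = c(NL = 0, LP = 0, LL = 0, LB = 0),
                    group_d = c(YOUNG = 0, OLDER = 0), inter = NULL,
                    subject_sd = 0, trial_sd = 0) {
    list(base = base, cond = cond, group_d = group_d, inter = inter,
         subject_sd = subject_sd, trial_sd = trial_sd)
  }
  defaults <- list(
    vas_likely = entry(8, cond = c(NL = 0, LP = 15, LL = 30, LB = 45),
                       subject_sd = 6, trial_sd = 5),
    vas_concern = entry(6, cond = c(NL = 0, LP = 14, LL = 28, LB = 42),
                        subject_sd = 6, trial_sd = 5),
    step_length = entry(0.55, cond = c(NL = 0, LP = 0, LL = -0.01, LB = -0.02),
                        inter = list(OLDER = c(LB = -0.02)),
                        subject_sd = 0.03, trial_sd = 0.015),
    step_width = entry(0.10, cond = c(NL = 0, LP = 0.005, LL = 0.015, LB = 0.03),
                       subject_sd = 0.01, trial_sd = 0.006),
    step_time = entry(0.40, subject_sd = 0.03, trial_sd = 0.02),
    prep_com_exc_ap = entry(0.015, cond = c(NL = 0, LP = 0.001, LL = 0.003, LB = 0.006),
                            subject_sd = 0.002, trial_sd = 0.001),
    prep_com_exc_ml = entry(0.008, cond = c(NL = 0, LP = 0.0005, LL = 0.0015, LB = 0.003),
                            subject_sd = 0.001, trial_sd = 0.0006),
    total_com_exc_ap = entry(0.25, subject_sd = 0.02, trial_sd = 0.01),
    total_com_exc_ml = entry(0.05,
                             inter = list(YOUNG = c(LL = 0.01, LB = 0.03),
                                          OLDER = c(LL = -0.004, LB = -0.01)),
                             subject_sd = 0.006, trial_sd = 0.004),
    exc_ankle = entry(20, cond = c(NL = 0, LP = -1, LL = -3, LB = -5),
                      subject_sd = 1.5, trial_sd = 0.8),
    exc_knee = entry(40, subject_sd = 3, trial_sd = 1.5),
    exc_hip = entry(50, cond = c(NL = 0, LP = 1, LL = 2, LB = 4),
                    subject_sd = 3, trial_sd = 1.5),
    exc_lumbar = entry(15, cond = c(NL = 0, LP = 2, LL = 5, LB = 8),
                       subject_sd = 1.5, trial_sd = 0.8),
    exc_thorax = entry(10, cond = c(NL = 0, LP = 1, LL = 2, LB = 3),
                       subject_sd = 1.2, trial_sd = 0.6),
    exc_shoulder = entry(70, subject_sd = 4, trial_sd = 2),
    exc_elbow = entry(30, subject_sd = 3, trial_sd = 1.5),
    # event-timing model (seconds)
    cop_on = entry(2.40, subject_sd = 0.05, trial_sd = 0.02),
    prep_duration = entry(0.40, subject_sd = 0.03, trial_sd = 0.015),
    # reach onset relative to step onset: positive = step precedes reach.
    # Older adults' steps follow the reaching arm under the double-lubricant
    # threat, hence the sign-flipping interaction.
    reach_delay = entry(0.08, inter = list(OLDER = c(LB = -0.16)),
                        subject_sd = 0.015, trial_sd = 0.008),
    reach_duration = entry(1.0, subject_sd = 0.05, trial_sd = 0.02)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    abort_config(paste0("unknown effect_config metric(s): ",
                        paste(bad, collapse = ", ")))
  for (nm in names(over)) defaults[[nm]] <- utils::modifyList(defaults[[nm]], over[[nm]])
  structure(defaults, class = "effect_config")
}

#' Channel-noise configuration for the synthetic cohort
#'
#' Measurement-noise magnitudes per stream, plus the EMG burst
#' signal-to-noise ratio (burst peak amplitude as a multiple of the raw EMG
#' baseline SD). `scale` multiplies every noise SD at once; `scale = 0` is
#' the noiseless generator (subject- and trial-level metric variability is
#' configured separately in [effect_config()]).
#'
#' @param emg_baseline_sd Raw EMG baseline noise SD, arbitrary units
#'   (default 0.02).
#' @param emg_burst_snr Burst peak amplitude / baseline SD (default 10).
#' @param force_sd Force-plate noise SD in newtons (default 2).
#' @param cop_sd Net-CoP noise SD in metres (default 0.001).
#' @param kin_sd Kinematic position noise SD in metres (default 0.001).
#' @param angle_sd Joint-angle noise SD in degrees (default 0.25).
#' @param scale Global multiplier on all noise SDs (default 1).
#' @return A `noise_config` list.
#' @export
noise_config <- function(emg_baseline_sd = 0.02, emg_burst_snr = 10,
                         force_sd = 2, cop_sd = 0.001, kin_sd = 0.001,
                         angle_sd = 0.25, scale = 1) {
  for (nm in c("emg_baseline_sd", "emg_burst_snr", "force_sd", "cop_sd",
               "kin_sd", "angle_sd", "scale")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      abort_config(sprintf("`%s` must be a single non-negative number", nm))
  }
  structure(
    list(emg_baseline_sd = emg_baseline_sd * scale,
         emg_burst_snr = emg_burst_snr,
         force_sd = force_sd * scale, cop_sd = cop_sd * scale,
         kin_sd = kin_sd * scale, angle_sd = angle_sd * scale),
    class = "noise_config"
  )
}

#' The 16-channel EMG inventory of the synthetic cohort
#'
#' Bilateral (L/R) erector spinae (ES), rectus abdominis (RA), tibialis
#' anterior (TA), gastrocnemius (GA), vastus lateralis (VL), biceps femoris
#' (BF), anterior deltoid (AD) and biceps brachii (BB).
#'
#' @return Character vector of 16 channel names.
#' @export
emg_channels <- function() {
  as.vector(outer(c("ES", "RA", "TA", "GA", "VL", "BF", "AD", "BB"),
                  c("L", "R"), paste, sep = "_"))
}

#' Specification of a synthetic step-and-reach cohort
#'
#' Defines the full design: participants per age group, the four blocked
#' surface conditions (no lubricant; lubricant under the planted leg; under
#' the landing area; both), trials per condition, the 8 s trial window, and
#' native sampling rates per stream (EMG 2000 Hz, force plates 1000 Hz,
#' kinematics 100 Hz).
#'
#' @param n_per_group Participants per group (default 10, minimum 2).
#' @param groups Group labels (default `c("YOUNG", "OLDER")`).
#' @param conditions Ordered condition labels, presented blocked
#'   (default `c("NL", "LP", "LL", "LB")`).
#' @param trials_per_condition Trials per condition (default 3).
#' @param duration_s Trial duration in seconds (default 8).
#' @param rates Named list of sampling rates in Hz
#'   (default `list(emg = 2000, force = 1000, kin = 100)`).
#' @param effects An [effect_config()].
#' @param noise A [noise_config()].
#' @param body_mass_kg Participant mass used for the force model (default 70).
#' @param seed Master seed; expanded per trial by a counter scheme so any
#'   trial can be regenerated independently (default 1).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 10, groups = c("YOUNG", "OLDER"),
                        conditions = c("NL", "LP", "LL", "LB"),
                        trials_per_condition = 3, duration_s = 8,
                        rates = list(emg = 2000, force = 1000, kin = 100),
                        effects = effect_config(), noise = noise_config(),
                        body_mass_kg = 70, seed = 1) {
  check_scalar_number(n_per_group, "n_per_group", positive = TRUE, integerish = TRUE)
  if (n_per_group < 2)
    abort_config("`n_per_group` must be >= 2 (within-group variance is needed)")
  if (!is.character(groups) || length(groups) < 1 || anyDuplicated(groups))
    abort_config("`groups` must be distinct labels")
  if (!is.character(conditions) || length(conditions) < 2 || anyDuplicated(conditions))
    abort_config("`conditions` must be >= 2 distinct ordered labels")
  check_scalar_number(trials_per_condition, "trials_per_condition",
                      positive = TRUE, integerish = TRUE)
  check_scalar_number(duration_s, "duration_s", positive = TRUE)
  for (nm in c("emg", "force", "kin")) {
    if (is.null(rates[[nm]]))
      abort_config(sprintf("`rates$%s` is required", nm))
    check_scalar_number(rates[[nm]], paste0("rates$", nm), positive = TRUE)
  }
  check_scalar_number(body_mass_kg, "body_mass_kg", positive = TRUE)
  check_scalar_number(seed, "seed", integerish = TRUE)
  structure(
    list(n_per_group = as.integer(n_per_group), groups = groups,
         conditions = conditions,
         trials_per_condition = as.integer(trials_per_condition),
         duration_s = duration_s, rates = rates, effects = effects,
         noise = noise, body_mass_kg = body_mass_kg,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d x %d participants, %s conditions x %d trials, %g s @ emg %g / force %g / kin %g Hz, seed %d\n",
    length(x$groups), x$n_per_group, paste(x$conditions, collapse = ">"),
    x$trials_per_condition, x$duration_s, x$rates$emg, x$rates$force,
    x$rates$kin, x$seed))
  invisible(x)
}
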