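# Shared fixtures: tiny cohort specs and hand-built envelopes.

tiny_spec <- function(seed = 1, ...) {
  cohort_spec(n_per_group = 2, trials_per_condition = 1, seed = seed, ...)
}

zero_noise_spec <- function(seed = 1, ...) {
  # channel noise off AND metric subject/trial variability off
  eff <- effect_config()
  for (m in names(eff)) {
    eff[[m]]$subject_sd <- 0
    eff[[m]]$trial_sd <- 0
  }
  cohort_spec(n_per_group = 2, trials_per_condition = 1,
              effects = eff, noise = noise_config(scale = 0), seed = seed, ...)
}

# Exhaustive reference implementation of the sustained supra-threshold onset
# rule: checks every candidate sample directly.
brute_force_onset <- function(envelope, k_sd, sustain_s, baseline_idx, rate) {
  base <- envelope[baseline_idx]
  thr <- mean(base) + k_sd * sd(base)
  n_sus <- max(1L, round(sustain_s * rate))
  for (t in seq_len(length(envelope) - n_sus + 1L)) {
    if (all(envelope[t:(t + n_sus - 1L)] > thr)) return((t - 1L) / rate)
  }
  NA_real_
}

# A smooth positive envelope with a known burst, for detector tests.
synthetic_envelope <- function(n = 2000, rate = 1000, baseline = 0.1,
                               noise_sd = 0.01, burst_at = NA, burst_amp = 1,
                               burst_len = 0.2, seed = 1) {
  withr::with_seed(seed, {
    e <- abs(baseline + rnorm(n, 0, noise_sd))
    if (!is.na(burst_at)) {
      t <- (seq_len(n) - 1) / rate
      e <- e + burst_amp * (t >= burst_at & t < burst_at + burst_len)
    }
    e
  })
}

# First-principles mixed-design score table generator (metric level).
random_mixed_scores <- function(n_per_group = 4, k = 4, g = 2, effect = 0,
                                trials = 1, sd_subj = 1, sd_trial = 1,
                                seed = 1) {
  withr::with_seed(seed, {
    conds <- paste0("c", seq_len(k))
    rows <- list()
    for (gi in seq_len(g)) for (pi in seq_len(n_per_group)) {
      pid <- sprintf("g%dp%d", gi, pi)
      u <- rnorm(1, 0, sd_subj)
      for (ci in seq_len(k)) for (tr in seq_len(trials)) {
        rows[[length(rows) + 1L]] <- data.frame(
          participant = pid, group = paste0("g", gi), condition = conds[ci],
          trial = tr,
          value = u + effect * (ci - 1) / (k - 1) + rnorm(1, 0, sd_trial))
      }
    }
    do.call(rbind, rows)
  })
}
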