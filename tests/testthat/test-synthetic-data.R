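test_that("cohort design has the blocked study layout and validates inputs", {
  spec <- cohort_spec()
  d <- cohort_design(spec)
  expect_equal(nrow(d), 2 * 10 * 4 * 3)      # groups x participants x conditions x trials
  # blocked condition order within each participant
  first <- d[d$participant == d$participant[1], ]
  expect_equal(first$condition, rep(c("NL", "LP", "LL", "LB"), each = 3))
  expect_error(cohort_spec(n_per_group = 1), "n_per_group")
  expect_error(cohort_spec(duration_s = -1), "duration_s")
  expect_error(cohort_spec(rates = list(emg = 2000, force = 1000)), "rates")
  expect_error(effect_config(bogus_metric = list(base = 1)), "unknown")
})

test_that("same seed gives bitwise-identical trials, different seeds differ", {
  spec <- tiny_spec(seed = 5)
  a <- generate_trial(spec, 1, 1, 1, 1)
  b <- generate_trial(spec, 1, 1, 1, 1)
  expect_identical(a$recording$emg, b$recording$emg)
  expect_identical(a$recording$force, b$recording$force)
  expect_identical(a$recording$kin, b$recording$kin)
  expect_identical(a$truth, b$truth)
  c_ <- generate_trial(tiny_spec(seed = 6), 1, 1, 1, 1)
  expect_false(identical(a$recording$emg$ES_L, c_$recording$emg$ES_L))
  # trial streams are independent: regenerating trial 2 alone matches the cohort
  spec2 <- cohort_spec(n_per_group = 2, trials_per_condition = 2, seed = 5)
  coh <- generate_cohort(spec2)
  d <- attr(coh, "design")
  i <- which(d$participant == "Y01" & d$condition == "LP" & d$trial == 2)
  solo <- generate_trial(spec2, d$group_i[i], d$part_i[i], d$cond_i[i], d$trial_i[i])
  expect_identical(coh[[i]]$recording$emg, solo$recording$emg)
})

test_that("EMG channel generator: baseline statistics, bursts, zero-noise support", {
  # rectified-envelope baseline mean close to the analytic sqrt(2/pi)*sd
  x <- generate_emg_channel(60, 2000, baseline_sd = 1, seed = 1, mains_frac = 0)
  expect_equal(mean(abs(x)), sqrt(2 / pi), tolerance = 0.01)
  expect_equal(sd(x), 1, tolerance = 0.01)

  # zero baseline noise: exactly zero outside the burst support
  y <- generate_emg_channel(4, 2000, baseline_sd = 0,
                            bursts = data.frame(onset_s = 2, duration_s = 0.2,
                                                amplitude = 1),
                            seed = 2)
  t <- (seq_along(y) - 1) / 2000
  expect_true(all(y[t < 2 | t > 2.2] == 0))
  expect_gt(max(abs(y)), 0)

  expect_error(generate_emg_channel(4, 2000, 1,
                                    bursts = data.frame(onset_s = 1,
                                                        duration_s = 0.2,
                                                        amplitude = -1)),
               "amplitude")
  expect_error(generate_emg_channel(4, 2000, 1,
                                    bursts = data.frame(onset_s = 3.9,
                                                        duration_s = 0.2,
                                                        amplitude = 1)),
               "within")
})

test_that("generated burst onsets are recovered by the conditioning + detector chain", {
  onset_true <- 3.0
  x <- generate_emg_channel(8, 2000, baseline_sd = 0.02,
                            bursts = data.frame(onset_s = onset_true,
                                                duration_s = 0.2,
                                                amplitude = 0.2),
                            seed = 11)
  env <- condition_emg(x, filter_spec(), 2000)
  onset <- detect_muscle_onset(env, onset_params(), 2000)
  expect_lt(abs(onset - onset_true), 0.010)
})

test_that("configured VAS slope and metric effects are recovered exactly at zero noise", {
  spec <- zero_noise_spec(seed = 9)
  # VAS likely: +15 mm per condition step by default -> LB - NL = 45 for everyone
  vas <- vapply(1:4, function(ci)
    generate_trial(spec, 1, 1, ci, 1)$recording$meta$vas_likely, numeric(1))
  expect_equal(vas[4] - vas[1], 45)
  expect_equal(diff(vas), c(15, 15, 15))

  # step width LB - NL = +0.03 m recovered through the full metric chain
  w <- vapply(c(1L, 4L), function(ci) {
    process_trial(generate_trial(spec, 1, 1, ci, 1)$recording)$movement$step_width
  }, numeric(1))
  expect_equal(w[2] - w[1], 0.03, tolerance = 1e-3)

  # quiet-stance vertical force equals body weight
  tr <- generate_trial(spec, 1, 1, 1, 1)
  fz_tot <- tr$recording$force$p1_fz + tr$recording$force$p2_fz
  expect_equal(mean(fz_tot[1:500]), spec$body_mass_kg * 9.81, tolerance = 1e-6)
})

test_that("ground-truth events sit on their constructed discontinuities", {
  spec <- zero_noise_spec(seed = 13)
  tr <- generate_trial(spec, 2, 1, 4, 1)   # OLDER, LB: reach precedes step
  p <- process_trial(tr$recording)
  truth <- tr$truth$events
  for (e in c("reach_on", "reach_off", "cop_on", "step_on", "step_off"))
    expect_lt(abs(p$events[[e]] - truth[[e]]), 0.002, label = e)
  # the OLDER/LB reach starts before the step (configured interaction)
  expect_lt(truth$reach_on, truth$step_on)
  # whereas YOUNG/LB steps first
  ty <- generate_trial(spec, 1, 1, 4, 1)$truth$events
  expect_gt(ty$reach_on, ty$step_on)
})

test_that("event ordering and VAS bounds hold across a random cohort", {
  spec <- cohort_spec(n_per_group = 3, trials_per_condition = 2, seed = 17)
  d <- cohort_design(spec)
  for (i in seq_len(nrow(d))) {
    tr <- generate_trial(spec, d$group_i[i], d$part_i[i], d$cond_i[i], d$trial_i[i])
    ev <- tr$truth$events
    expect_true(ev$cop_on <= ev$step_on && ev$step_on < ev$step_off &&
                  ev$step_off <= ev$reach_off)
    expect_true(all(unlist(ev) >= 0 & unlist(ev) <= spec$duration_s))
    expect_true(tr$recording$meta$vas_likely >= 0 &&
                  tr$recording$meta$vas_likely <= 100)
  }
})
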