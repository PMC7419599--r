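test_that("onset detector finds sustained bursts and rejects short ones", {
  rate <- 1000
  # 10-sigma burst starting at 1.0 s, 200 ms long
  env <- synthetic_envelope(n = 2000, rate = rate, burst_at = 1.0,
                            burst_amp = 0.1, burst_len = 0.2, seed = 2)
  onset <- detect_muscle_onset(env, onset_params(), rate)
  expect_lt(abs(onset - 1.0), 0.010)

  # 8-sigma burst lasting only 40 ms fails the 50 ms sustain rule
  env40 <- synthetic_envelope(n = 2000, rate = rate, burst_at = 1.0,
                              burst_amp = 0.08, burst_len = 0.040, seed = 3)
  expect_true(is.na(detect_muscle_onset(env40, onset_params(), rate)))

  # flat envelope at the baseline mean -> none, zero-variance baseline with
  # off-baseline activity -> degenerate-baseline error
  expect_true(is.na(detect_muscle_onset(rep(0.5, 2000), onset_params(), rate)))
  degen <- c(rep(0.5, 1000), rep(5, 1000))
  expect_error(detect_muscle_onset(degen, onset_params(), rate), "degenerate")
})

test_that("onset detector equals the exhaustive brute-force scan", {
  rate <- 1000
  params <- onset_params(baseline_window = c(0, 0.5))
  for (s in 1:40) {
    has_burst <- s %% 2 == 0
    env <- synthetic_envelope(
      n = 1500, rate = rate, noise_sd = 0.015,
      burst_at = if (has_burst) 0.6 + (s %% 7) * 0.1 else NA,
      burst_amp = 0.05 + 0.05 * (s %% 3), burst_len = 0.03 + 0.02 * (s %% 5),
      seed = 100 + s)
    expect_identical(
      detect_muscle_onset(env, params, rate),
      brute_force_onset(env, params$k_sd, params$sustain_s, 1:500, rate),
      label = sprintf("case %d", s))
  }
})

test_that("raising k_sd or sustain_s never advances an onset (monotonicity)", {
  rate <- 1000
  for (s in 1:10) {
    env <- synthetic_envelope(n = 2000, rate = rate, burst_at = 0.8,
                              burst_amp = 0.12, burst_len = 0.15, seed = s)
    o1 <- detect_muscle_onset(env, onset_params(k_sd = 5), rate)
    o2 <- detect_muscle_onset(env, onset_params(k_sd = 9), rate)
    if (!is.na(o1) && !is.na(o2)) expect_gte(o2, o1)
    s1 <- detect_muscle_onset(env, onset_params(sustain_s = 0.02), rate)
    s2 <- detect_muscle_onset(env, onset_params(sustain_s = 0.10), rate)
    if (is.na(s1)) expect_true(is.na(s2))
  }
})

test_that("latencies are signed relative to reach onset", {
  ev <- event_set(reach_on = 3.0, reach_off = 4.0)
  lat <- onsets_relative_to_reach(c(a = 2.8, b = 3.1), ev)
  expect_equal(unname(lat), c(-0.2, 0.1))
  expect_error(onsets_relative_to_reach(2.8, event_set()), "reach_on")
})

test_that("CCI matches hand-computed values, is symmetric, amplitude-weighted", {
  expect_equal(compute_cci(c(0.2, 0.4), c(0.1, 0.4)), mean(c(0.15, 0.8)))
  expect_equal(compute_cci(c(0, 0), c(0, 0)), 0)
  expect_equal(compute_cci(rep(0.5, 10), rep(0.5, 10)), 1.0)
  # antagonist silent -> 0
  expect_equal(compute_cci(c(0.3, 0.9), c(0, 0)), 0)
  withr::with_seed(9, {
    a <- runif(50); b <- runif(50)
    expect_equal(compute_cci(a, b), compute_cci(b, a))
    # doubling both envelopes doubles the weighted CCI (documented non-scale-invariance)
    expect_equal(compute_cci(2 * a, 2 * b), 2 * compute_cci(a, b))
    # the plain ratio variant IS scale invariant
    expect_equal(compute_cci(2 * a, 2 * b, method = "ratio"),
                 compute_cci(a, b, method = "ratio"))
  })
  expect_error(compute_cci(1:3 / 3, 1:2 / 2), "mismatched")
})

test_that("phase-windowed CCI maps phases i-iv and tags roles", {
  rate <- 100
  n <- 800
  ev <- event_set(reach_on = 3.0, reach_off = 4.5)
  t <- (seq_len(n) - 1) / rate
  # co-activation only after reach onset
  a <- as.numeric(t >= 3.0) * 0.5
  b <- as.numeric(t >= 3.0) * 0.5
  res <- cci_by_phase(a, b, rate, ev)
  expect_equal(res$phase, c("i", "ii", "iii", "iv"))
  expect_equal(res$role, c("preparatory", "preparatory",
                           "compensatory", "compensatory"))
  expect_equal(res$cci[1:2], c(0, 0))
  expect_gt(res$cci[3], 0)

  # constant equal envelopes -> all four phases identical
  resc <- cci_by_phase(rep(0.4, n), rep(0.4, n), rate, ev)
  expect_equal(length(unique(round(resc$cci, 12))), 1L)

  # window outside the trial is an error
  ev_bad <- event_set(reach_on = 0.6, reach_off = 2.0)
  expect_error(cci_by_phase(a, b, rate, ev_bad), "outside")
})
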