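test_that("reach events come from sensor edges and enforce ordering", {
  rate <- 1000
  s <- numeric(6000)
  s[3001:4500] <- 1                     # rising edge at sample 3001 (t = 3.0 s)
  ev <- detect_reach_events(s, rate)
  expect_equal(unname(ev), c(3.0, 4.5))
  expect_error(detect_reach_events(numeric(100), rate), "unanalyzable")
  expect_error(detect_reach_events(c(rep(1, 50), rep(0, 50)), rate),
               "unanalyzable")
  expect_error(detect_reach_events(c(0, 2, 0), rate), "binary")
})

test_that("CoP onset detects a noiseless ramp exactly and flags pure noise", {
  rate <- 1000
  t <- (0:5999) / rate
  ramp <- 0.03 * pmin(1, pmax(0, (t - 2.5) / 0.15))
  cop <- data.frame(ap = numeric(length(t)), ml = ramp)
  expect_lt(abs(detect_cop_onset(cop, rate) - 2.5), 1.5 / rate)

  withr::with_seed(5, {
    noise <- data.frame(ap = rnorm(6000, 0, 1e-3), ml = rnorm(6000, 0, 1e-3))
    expect_warning(on_na <- detect_cop_onset(noise, rate), "no CoP deviation")
    expect_true(is.na(on_na))
  })
})

test_that("CoP onset error stays small at signal-to-noise 5", {
  rate <- 1000
  t <- (0:5999) / rate
  amp <- 0.03
  errs <- vapply(1:100, function(s) {
    withr::with_seed(1000 + s, {
      cop <- data.frame(
        ap = rnorm(6000, 0, amp / 5 / 3),
        ml = amp * pmin(1, pmax(0, (t - 2.5) / 0.15)) + rnorm(6000, 0, amp / 5))
      # noisy-plate configuration: 10 Hz pre-smoothing with the sustain
      # requirement stretched to match the smoothed noise correlation time
      detect_cop_onset(cop, rate, sustain_s = 0.1, lp_hz = 10) - 2.5
    })
  }, numeric(1))
  expect_lt(median(abs(errs)), 0.020)
})

test_that("step events recover the constructed unloading and landing times", {
  rate <- 1000
  t <- (0:5999) / rate
  bw <- 700; f0 <- bw / 2
  s_un <- 0.015; s_re <- 0.010
  fz <- f0 * (1 - plogis((t - (3.2 - s_un * log(19))) / s_un)) +
    0.4 * bw * plogis((t - (3.6 + s_re * log(7))) / s_re)
  ev <- detect_step_events(fz, rate, bw)
  expect_lt(abs(ev[["step_on"]] - 3.2), 0.003)
  expect_lt(abs(ev[["step_off"]] - 3.6), 0.003)
  expect_equal(unname(ev[["step_off"]] - ev[["step_on"]]), 0.4, tolerance = 0.01)
  expect_error(detect_step_events(rep(f0, 6000), rate, bw), "never unloads")
})

test_that("step characteristics are malleoli distances at landing", {
  mal <- data.frame(time = seq(0, 5, by = 0.01),
                    support_ap = 0, support_ml = 0,
                    landing_ap = 0.6, landing_ml = 0.12)
  ev <- event_set(step_on = 3.2, step_off = 3.6)
  sc <- compute_step_characteristics(mal, ev)
  expect_equal(sc$step_length, 0.6)
  expect_equal(sc$step_width, 0.12)
  expect_equal(sc$step_time, 0.4)
  # same AP coordinate -> zero step length
  mal$landing_ap <- 0
  expect_equal(compute_step_characteristics(mal, ev)$step_length, 0)
  expect_error(compute_step_characteristics(mal[, 1:3], ev), "missing column")
})

test_that("event detection is translation-equivariant and truth-consistent", {
  spec <- tiny_spec(seed = 21)
  tr <- generate_trial(spec, 1, 1, 2, 1)
  p <- process_trial(tr$recording)
  truth <- tr$truth$events
  for (e in c("reach_on", "reach_off", "cop_on", "step_on", "step_off")) {
    expect_lt(abs(p$events[[e]] - truth[[e]]), 0.010, label = e)
  }
  # ordering invariant on an analyzable trial
  expect_lte(p$events$cop_on, p$events$step_on)
  expect_lt(p$events$step_on, p$events$step_off)

  # shifting the CoP stream shifts the detected onset by the same amount
  rate <- 1000
  t <- (0:5999) / rate
  mk <- function(shift) {
    withr::with_seed(77, data.frame(
      ap = rnorm(6000, 0, 5e-4),
      ml = 0.03 * pmin(1, pmax(0, (t - 2.0 - shift) / 0.15)) +
        rnorm(6000, 0, 5e-4)))
  }
  d0 <- detect_cop_onset(mk(0), rate)
  d1 <- detect_cop_onset(mk(0.5), rate)
  expect_equal(d1 - d0, 0.5, tolerance = 0.005)
})
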