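test_that("preparatory CoM metrics: ramps, constants, analytic cases", {
  t <- seq(0, 8, by = 0.01)
  ev <- event_set(reach_on = 3.0, reach_off = 4.0, cop_on = 2.4,
                  step_on = 2.8, step_off = 3.2)
  # linear ramp 0 -> 0.02 across the prep interval: excursion 0.02, acc ~ 0
  ramp <- approx(c(0, 2.4, 2.8, 8), c(0, 0, 0.02, 0.02), xout = t)$y
  com <- data.frame(time = t, ap = ramp, ml = 0)
  m <- preparatory_com_metrics(com, ev)
  expect_equal(m$prep_com_exc_ap, 0.02, tolerance = 1e-9)
  expect_equal(m$prep_com_exc_ml, 0)
  # the ramp's corners hold all the curvature; inside the interval the SG
  # second derivative is tiny relative to a real postural acceleration
  expect_lt(m$prep_com_acc_ml, 1e-9)

  # constant CoM -> all metrics zero
  m0 <- preparatory_com_metrics(data.frame(time = t, ap = 1, ml = -1), ev)
  expect_equal(unlist(m0[c("prep_com_exc_ap", "prep_com_exc_ml",
                           "prep_com_acc_ap", "prep_com_acc_ml")]),
               c(prep_com_exc_ap = 0, prep_com_exc_ml = 0,
                 prep_com_acc_ap = 0, prep_com_acc_ml = 0))

  # degenerate interval -> missing metrics with a warning
  ev2 <- event_set(cop_on = 2.4, step_on = 2.41, step_off = 3.2)
  expect_warning(mna <- preparatory_com_metrics(com, ev2), "shorter than 3")
  expect_true(all(is.na(unlist(mna))))
})

test_that("total excursion is peak-to-peak on the movement interval", {
  t <- seq(0, 8, by = 0.01)
  ev <- event_set(reach_on = 3.0, reach_off = 5.0, cop_on = 2.0,
                  step_on = 2.8, step_off = 3.2)
  com <- data.frame(time = t, ap = 0.1 * sin(2 * pi * (t - 2) / 3),
                    ml = approx(c(0, 2, 5, 8), c(0.2, 0.2, 0.5, 0.5), xout = t)$y)
  tot <- total_com_excursion(com, ev)
  expect_equal(tot$total_com_exc_ap, 0.2, tolerance = 1e-3)  # sinusoid: 2A
  expect_equal(tot$total_com_exc_ml, 0.3, tolerance = 1e-9)  # ramp: |b - a|
})

test_that("joint excursions are per-joint peak-to-peak with missing flagged", {
  t <- seq(0, 8, by = 0.01)
  ev <- event_set(reach_on = 3.0, reach_off = 5.0, cop_on = 2.0,
                  step_on = 2.8, step_off = 3.2)
  joints <- data.frame(time = t, ankle = 12,
                       lumbar = approx(c(0, 2, 5, 8), c(10, 10, 25, 25),
                                       xout = t)$y)
  expect_warning(
    exc <- peak_joint_excursions(joints, ev,
                                 joint_names = c("ankle", "lumbar", "knee")),
    "knee")
  expect_equal(exc$exc_ankle, 0)
  expect_equal(exc$exc_lumbar, 15, tolerance = 1e-9)
  expect_true(is.na(exc$exc_knee))
})

test_that("peak-to-peak invariances: translation, scaling, window monotonicity", {
  t <- seq(0, 8, by = 0.01)
  ev <- event_set(reach_on = 3.0, reach_off = 5.0, cop_on = 2.0,
                  step_on = 2.8, step_off = 3.2)
  withr::with_seed(4, {
    x <- cumsum(rnorm(length(t), 0, 0.01))
    com <- data.frame(time = t, ap = x, ml = x)
    base <- total_com_excursion(com, ev)
    shifted <- total_com_excursion(
      data.frame(time = t, ap = x + 5, ml = x - 2), ev)
    expect_equal(base, shifted)
    scaled <- total_com_excursion(
      data.frame(time = t, ap = 3 * x, ml = 3 * x), ev)
    expect_equal(scaled$total_com_exc_ap, 3 * base$total_com_exc_ap)
    wider <- total_com_excursion(com, ev, interval = c(1.5, 6.0))
    expect_gte(wider$total_com_exc_ap, base$total_com_exc_ap)
  })
})

test_that("preparatory excursion never exceeds total excursion on cohort trials", {
  spec <- tiny_spec(seed = 31)
  for (ci in c(1L, 4L)) {
    tr <- generate_trial(spec, 1, 1, ci, 1)
    p <- process_trial(tr$recording)
    expect_lte(p$movement$prep_com_exc_ap,
               p$movement$total_com_exc_ap + 1e-12)
    expect_lte(p$movement$prep_com_exc_ml,
               p$movement$total_com_exc_ml + 1e-12)
  }
})
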