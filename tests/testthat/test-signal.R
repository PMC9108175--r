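make_raw <- function(ax, ay, az, n = 30, hz = 30) {
  data.frame(t_s = (seq_len(n) - 1) / hz, ax_g = ax, ay_g = ay, az_g = az)
}

test_that("ENMO subtracts gravity and floors negatives at zero", {
  expect_equal(compute_enmo(make_raw(0.6, 0.8, 0))$enmo_mg, 0)
  expect_equal(compute_enmo(make_raw(1.2, 0, 0))$enmo_mg, 200)
  expect_equal(compute_enmo(make_raw(0.5, 0, 0))$enmo_mg, 0) # not -500
})

test_that("ENMO is invariant to rotation of the axes", {
  set.seed(1)
  raw <- make_raw(rnorm(300, 0.6, 0.2), rnorm(300, 0.7, 0.2),
                  rnorm(300, 0.2, 0.2), n = 300)
  th <- 0.7
  rot <- raw
  rot$ax_g <- cos(th) * raw$ax_g - sin(th) * raw$ay_g
  rot$ay_g <- sin(th) * raw$ax_g + cos(th) * raw$ay_g
  expect_equal(compute_enmo(rot)$enmo_mg, compute_enmo(raw)$enmo_mg,
               tolerance = 1e-12)
})

test_that("vector magnitude is the Euclidean norm of the count triplet", {
  expect_equal(vector_magnitude(3, 4, 0), 5)
  expect_equal(vector_magnitude(0, 0, 0), 0)
  expect_equal(vector_magnitude(100, 100, 100), 100 * sqrt(3))
  expect_equal(vector_magnitude(7, 0, 0), 7) # identity on one axis
  expect_error(vector_magnitude(-1, 0, 0), "non-negative")
  # monotone non-decreasing in each argument
  g <- expand.grid(a = c(0, 5, 50), b = c(0, 10), c = c(0, 3))
  vm <- vector_magnitude(g$a, g$b, g$c)
  expect_true(all(vector_magnitude(g$a + 1, g$b, g$c) >= vm))
  expect_true(all(vector_magnitude(g$a, g$b + 1, g$c) >= vm))
})

test_that("analysis windows are the published 120-s intervals", {
  expect_equal(analysis_window("RU"), c(150, 270))
  expect_equal(analysis_window("CW"), c(150, 270))
  expect_equal(analysis_window("LD"), c(420, 540))
  for (code in activity_profiles()$code)
    expect_equal(diff(analysis_window(code)), 120)
  expect_error(analysis_window("RU", duration_s = 200), "window")
})

test_that("steady state applies the 5-bpm and 10-percent tolerances", {
  expect_true(steady_state_check(rep(120, 8), rep(900, 8)))
  # hr oscillating 114-126: deviation 6 bpm from the mean of 120
  expect_false(steady_state_check(rep(c(114, 126), 4), rep(900, 8)))
  # vo2 900-1020 around mean 960: 6.25 % deviation, inside the 10 % band
  expect_true(steady_state_check(rep(120, 8), rep(c(900, 1020), 4)))
  # 12 % deviation fails
  expect_false(steady_state_check(rep(120, 8), rep(c(880, 1120), 4)))
  expect_error(steady_state_check(120, 900), "2 samples")
})

test_that("autocalibration leaves calibrated static input unchanged", {
  raw <- simulate_static_postures(seed = 2)
  cal <- autocalibrate(raw)
  expect_true(cal$converged)
  expect_equal(cal$gain, c(1, 1, 1), tolerance = 5e-3)
  expect_equal(cal$offset, c(0, 0, 0), tolerance = 5e-3)
})

test_that("autocalibration recovers a known gain/offset distortion", {
  err <- calibration_error(gain = c(1.05, 0.95, 1.02),
                           offset = c(0.02, -0.03, 0))
  raw <- wristcutpoints:::distort_raw(simulate_static_postures(seed = 3),
                                      err)
  cal <- autocalibrate(raw)
  expect_true(cal$converged)
  expect_true(all(abs(cal$gain - err$gain) < 0.01))
  expect_true(all(abs(cal$offset - err$offset) < 0.01))
})

test_that("degenerate inputs return the identity, unconverged", {
  # pure dynamic signal: no still windows at all
  set.seed(9)
  n <- 90 * 30
  dyn <- data.frame(t_s = (seq_len(n) - 1) / 30,
                    ax_g = rnorm(n, 0, 0.5), ay_g = rnorm(n, 0, 0.5),
                    az_g = rnorm(n, 1, 0.5))
  cal <- autocalibrate(dyn)
  expect_false(cal$converged)
  expect_equal(cal$gain, c(1, 1, 1))
  expect_equal(cal$offset, c(0, 0, 0))

  # a single posture is still but orientation-poor: cannot separate
  # gain from offset, so the identity is returned
  one <- make_raw(0.1, 0.1, 0.99, n = 90 * 30)
  one[, 2:4] <- one[, 2:4] + rnorm(3 * nrow(one), 0, 0.003)
  expect_false(autocalibrate(one)$converged)

  expect_error(autocalibrate(make_raw(1, 0, 0, n = 30)), "60 s")
})

test_that("recalibrating already-calibrated data barely changes ENMO", {
  tr <- generate_trial(fixture_participant(), fixture_profile("SW"),
                       seed = 13)
  raw <- tr$raw$left
  cal <- autocalibrate(raw)
  cal <- if (cal$converged) cal else identity_calibration()
  e0 <- compute_enmo(raw)$enmo_mg
  e1 <- compute_enmo(apply_calibration(raw, cal))$enmo_mg
  expect_lt(median(abs(e1 - e0)), 1)
})

test_that("trial summaries are window means of the epoch series", {
  tr <- fixture_constant_trial(va = 250)
  fx <- summarize_trial(tr, cal = identity_cal_pair())
  expect_equal(nrow(fx), 2)
  expect_equal(fx$mean_va, c(250, 250))
  expect_equal(fx$mean_enmo, c(0, 0))
  expect_equal(fx$mean_vo2, c(900, 900))
  expect_true(all(fx$steady_state))

  # alternating 200/300 counts average to 250 over the 24-epoch window
  tr2 <- fixture_constant_trial(va = rep(c(200, 300), 30))
  fx2 <- summarize_trial(tr2, cal = identity_cal_pair())
  expect_equal(fx2$mean_va[1], 250)

  # VM formed per epoch from the triplet
  tr3 <- fixture_constant_trial(va = 3, ml = 4, ap = 0)
  expect_equal(summarize_trial(tr3, cal = identity_cal_pair())$mean_vm[1], 5)
})

test_that("generator lying-down trials summarize to near-zero counts", {
  tr <- generate_trial(fixture_participant(), fixture_profile("LD"),
                       seed = 3)
  fx <- summarize_trial(tr, cal = identity_cal_pair())
  expect_true(all(fx$mean_va < 35))
})
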