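fs <- 2048

test_that("Butterworth low-pass has unit DC gain and the textbook cutoff", {
  x <- rep(3.7, 4 * fs)
  expect_equal(filter_torque(x, fs)[fs:(3 * fs)], rep(3.7, 2 * fs + 1),
               tolerance = 1e-6)
  # single-pass magnitude at the 50 Hz cutoff: 1/sqrt(2)
  t <- seq(0, 4, by = 1 / fs)
  s50 <- sin(2 * pi * 50 * t)
  y <- filter_torque(s50, fs, zero_phase = FALSE)
  steady <- y[(2 * fs):(4 * fs)]
  amp <- sqrt(2 * mean(steady^2))
  expect_equal(amp, 1 / sqrt(2), tolerance = 0.01)
  # zero-phase (two-pass) variant squares the magnitude: 1/2
  y2 <- filter_torque(s50, fs, zero_phase = TRUE)
  amp2 <- sqrt(2 * mean(y2[(2 * fs):(3 * fs)]^2))
  expect_equal(amp2, 1 / 2, tolerance = 0.02)
})

test_that("a 200 Hz tone is attenuated by about three orders of magnitude", {
  t <- seq(0, 4, by = 1 / fs)
  y <- filter_torque(sin(2 * pi * 200 * t), fs, zero_phase = FALSE)
  amp <- sqrt(2 * mean(y[(2 * fs):(4 * fs)]^2))
  # analog closed form gives (1 + 4^10)^(-1/2) ~ 9.8e-4; the digital design
  # warps the stopband slightly, so check the magnitude bracket
  expect_lt(amp, 1.5e-3)
  expect_gt(amp, 0.5e-3)
})

test_that("filters are linear and reject too-low sampling rates", {
  set.seed(1)
  a <- stats::rnorm(fs); b <- stats::rnorm(fs)
  expect_equal(filter_torque(a + b, fs),
               filter_torque(a, fs) + filter_torque(b, fs), tolerance = 1e-9)
  expect_error(filter_torque(a, fs = 90), "cutoff")
})

test_that("feedback moving average reproduces constants and kills Nyquist", {
  x <- rep(5, 1000)
  expect_equal(feedback_smooth(x, fs), x) # DC gain exactly 1, edges included
  # unit step: linear rise across the 125 ms window
  n <- 4 * fs
  step <- c(rep(0, n / 2), rep(1, n / 2))
  y <- feedback_smooth(step, fs)
  w <- round(0.125 * fs)
  ramp_region <- y[(n / 2 - w):(n / 2 + w)]
  expect_true(all(diff(ramp_region) >= 0))
  expect_lt(max(abs(diff(ramp_region))), 2 / w)
  # alternating +-1 at Nyquist averages out
  alt <- rep(c(1, -1), length.out = n)
  mid <- feedback_smooth(alt, fs)[(w + 1):(n - w)]
  expect_lt(max(abs(mid)), 1 / 256)
})

test_that("torque CV matches closed forms and is scale invariant", {
  # constant torque: CV = 0
  tr <- torque_trace(seq(0, 1, by = 1 / fs), rep(4, fs + 1), mvt = 40,
                     fs = fs, filter = FALSE)
  expect_equal(torque_cv(tr, c(0, 1)), 0)
  # 10 + 0.5 sin(2 pi t) %MVT over whole cycles: 100*(0.5/sqrt(2))/10
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  pct <- 10 + 0.5 * sin(2 * pi * t)
  tr2 <- torque_trace(t, pct * 40 / 100, mvt = 40, fs = fs, filter = FALSE)
  expect_equal(torque_cv(tr2, c(0, 8)), 100 * (0.5 / sqrt(2)) / 10,
               tolerance = 0.001)
  # hand computation on {9, 10, 11} with sample SD
  tr3 <- torque_trace(c(0, 1, 2), c(9, 10, 11), mvt = 100, fs = 1,
                      filter = FALSE)
  expect_equal(torque_cv(tr3, c(0, 2)), 10)
  # scale invariance: multiplying torque by k > 0 leaves CV unchanged
  tr4 <- torque_trace(t, 3 * pct * 40 / 100, mvt = 40, fs = fs,
                      filter = FALSE)
  expect_equal(torque_cv(tr4, c(0, 8)), torque_cv(tr2, c(0, 8)))
})

test_that("non-positive mean torque in a window is rejected", {
  tr <- torque_trace(c(0, 1, 2), c(-1, 0, 1), mvt = 10, fs = 1,
                     filter = FALSE)
  expect_error(torque_cv(tr, c(0, 2)), "mean")
})

test_that("plateau windows come from the command, holds match sombreros", {
  smb <- generate_command("sombrero", 10, 30, 3, 10)
  w <- segment_plateaus(smb)
  expect_equal(w$plateau_one, c(0, 10))
  expect_equal(w$ramp, c(10, 10 + 40 / 3))
  expect_equal(w$plateau_two, c(10 + 40 / 3, 20 + 40 / 3))
  hold <- generate_command("hold", 10, 30, 3, 10)
  expect_equal(segment_plateaus(hold), w)
  expect_error(segment_plateaus(generate_command("ramp", 0, 30, 3)),
               "plateau")
})

test_that("delta CV subtracts plateau CVs (trimmed windows)", {
  smb <- generate_command("sombrero", 10, 30, 3, 10)
  w <- segment_plateaus(smb)
  t <- smb$t
  # build 10% MVT with sinusoidal ripple: amplitude 0.25 in plateau one,
  # 0.4 in plateau two -> CVs 100*(A/sqrt(2))/10 each
  pct <- rep(10, length(t))
  p1 <- t >= w$plateau_one[1] & t <= w$plateau_one[2]
  p2 <- t >= w$plateau_two[1] & t <= w$plateau_two[2]
  pct[p1] <- 10 + 0.25 * sin(2 * pi * 2 * t[p1])
  pct[p2] <- 10 + 0.40 * sin(2 * pi * 2 * t[p2])
  tr <- torque_trace(t, pct * 40 / 100, mvt = 40, fs = fs, filter = FALSE)
  expected <- 100 * (0.4 / sqrt(2)) / 10 - 100 * (0.25 / sqrt(2)) / 10
  expect_equal(delta_cv(tr, w), expected, tolerance = 0.02)
  # identical statistics in both plateaus -> 0
  pct[p2] <- 10 + 0.25 * sin(2 * pi * 2 * (t[p2] - w$plateau_two[1]))
  tr0 <- torque_trace(t, pct * 40 / 100, mvt = 40, fs = fs, filter = FALSE)
  expect_equal(delta_cv(tr0, w), 0, tolerance = 5e-3)
})

test_that("deviating trials are flagged, compliant trials are not", {
  cmd <- generate_command("hold", 10, 30, 3, 10)
  good <- trace_from_command(cmd)
  expect_false(flag_deviating_trial(good, cmd))
  bad <- torque_trace(cmd$t, (command_drive_at(cmd, cmd$t) + 8) * 40 / 100,
                      mvt = 40, fs = cmd$fs, filter = FALSE)
  expect_true(flag_deviating_trial(bad, cmd))
})
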