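smb <- generate_command("sombrero", 10, 30, 3, 10)
win <- segment_plateaus(smb)

test_that("discharge end scans ISIs for the first >= 1 s gap", {
  expect_equal(discharge_end(regular_train(10, 0, 5)), 5)
  expect_equal(discharge_end(spike_train(c(19, 19.5, 20, 21.5, 21.6))), 20)
  # a gap of exactly 1 s terminates maintained discharge
  expect_equal(discharge_end(spike_train(c(0, 0.5, 1.5, 1.6))), 0.5)
  expect_equal(discharge_end(spike_train(3.2)), 3.2)
  expect_error(discharge_end(spike_train(numeric(0))), "empty")
})

test_that("brim/button/cap classification follows recruitment and extent", {
  trains <- list(
    regular_train(10, 2, 30, "brim1"),        # recruited in plateau one
    regular_train(10, 14, 20, "button1"),     # within the centre ramp
    regular_train(10, 14, 30, "cap1"),        # ramp into plateau two
    regular_train(10, 25, 32, "other1"))      # recruited in plateau two
  cats <- classify_units(trains, win)
  expect_equal(cats$category,
               c("brim", "button", "cap", "other"))
  # a ramp unit whose maintained discharge breaks before plateau two is a
  # button even if stray late spikes exist
  broken <- spike_train(c(seq(14, 20, by = 0.1), 24, 24.1), "broken")
  expect_equal(classify_units(list(broken), win)$category, "button")
})

test_that("noiseless simulation classification matches ground truth", {
  for (s in 1:4) {
    set.seed(s)
    cfg <- pool_config(n_units = 15, hysteresis = stats::runif(15, 0, 4),
                       isi_cv = 0, seed = s)
    sim <- simulate_pool(cfg, smb)
    nonempty <- lengths(lapply(sim$trains, `[[`, "times")) > 0
    cats <- classify_units(sim$trains[nonempty], win)
    expect_equal(cats$category, sim$truth$category[nonempty])
  }
})

test_that("sustained duration matches the piecewise-linear arithmetic", {
  # recruited at 15% on the ascending ramp (t = 11.667 s); the command falls
  # back to 15% at t = 21.667 s; maintained discharge to 33 s
  train <- regular_train(12, 10 + 5 / 3, 33, "u")
  sd_res <- sustained_duration(train, windows = win, cmd = smb)
  expect_equal(sd_res$t_theoretical_derec, 20 + 5 / 3, tolerance = 1e-9)
  expect_equal(sd_res$sustained_dur, 33 - (20 + 5 / 3), tolerance = 1e-9)
  # derecruited exactly at the descending crossing -> 0
  train0 <- regular_train(12, 10 + 5 / 3, 20 + 5 / 3, "u")
  expect_equal(sustained_duration(train0, windows = win, cmd = smb)$sustained_dur,
               0, tolerance = 1e-9)
})

test_that("sustained duration from measured torque matches the command", {
  tr <- trace_from_command(smb)
  train <- regular_train(12, 10 + 5 / 3, 33, "u")
  sd_tq <- sustained_duration(train, trace = tr, windows = win)
  expect_equal(sd_tq$t_theoretical_derec, 20 + 5 / 3, tolerance = 2 / 2048)
  expect_false(sd_tq$no_crossing)
  # torque that never falls back to the recruitment level -> flagged
  t2 <- seq(0, 20, by = 1 / 256)
  tq2 <- ifelse(t2 <= 10, 3 * t2, 30 - 1.5 * (t2 - 10)) # ends at 15%
  tr2 <- torque_trace(t2, tq2, mvt = 100, fs = 256, filter = FALSE)
  low <- regular_train(12, 2, 19, "b") # recruited at 6% on the way up
  s_low <- sustained_duration(low, trace = tr2, windows = NULL)
  expect_true(s_low$no_crossing)
  expect_true(is.na(s_low$sustained_dur))
})

test_that("zero-hysteresis simulated units sustain for ~0 s", {
  cfg <- pool_config(n_units = 4, hysteresis = 0, isi_cv = 0,
                     threshold_range = c(12, 25), seed = 3)
  sim <- simulate_pool(cfg, smb)
  for (train in sim$trains) {
    s <- sustained_duration(train, windows = win, cmd = smb)
    expect_equal(s$sustained_dur, 0, tolerance = 1 / 2048 * 3)
  }
})

test_that("proportion of sustained units uses the ramp denominator", {
  cats <- data.frame(
    unit_id = c(paste0("c", 1:4), paste0("b", 1:6), paste0("br", 1:5)),
    category = c(rep("cap", 4), rep("button", 6), rep("brim", 5)),
    stringsAsFactors = FALSE)
  sus <- lapply(1:4, function(i) {
    structure(list(unit_id = paste0("c", i),
                   sustained_dur = c(5, 3, 2.5, 1)[i]),
              class = "sustained_discharge")
  })
  # 3 caps exceed 2 s; 10 units recruited in the ramp
  expect_equal(proportion_sustained(cats, sus), 0.3)
  # alternative denominator: cap + brim = 9
  expect_equal(proportion_sustained(cats, sus, denominator = "cap_brim"),
               3 / 9)
  # no caps -> 0; empty denominator -> NA with warning
  none <- cats[cats$category == "brim", ]
  expect_equal(proportion_sustained(cats[cats$category != "cap", ], list()),
               0)
  expect_warning(p <- proportion_sustained(none, list()), "denominator")
  expect_true(is.na(p))
})

test_that("plateau rate delta averages the smoothed curve per plateau", {
  t <- smb$t
  u <- make_mu(t, ifelse(t < win$ramp[1], 12,
                         ifelse(t > win$plateau_two[1], 10, 14)),
               0, max(t), "brim1")
  res <- plateau_rate_delta(list(u), win)
  expect_equal(res$delta_rate, -2, tolerance = 1e-4)
  # unit absent from plateau two is excluded with a reason
  tt <- t[t <= 15]
  u2 <- make_mu(tt, rep(12, length(tt)), 0, 15, "short")
  res2 <- plateau_rate_delta(list(u2), win)
  expect_equal(res2$excluded_reason, "inactive_plateau_two")
  expect_true(is.na(res2$delta_rate))
})
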