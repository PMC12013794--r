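test_that("zero-hysteresis units have symmetric recruitment/derecruitment", {
  cfg <- pool_config(n_units = 6, hysteresis = 0, isi_cv = 0,
                     threshold_range = c(5, 25), seed = 7)
  cmd <- generate_command("ramp", 0, 30, 3)
  sim <- simulate_pool(cfg, cmd)
  for (i in seq_len(cfg$n_units)) {
    tr <- sim$trains[[i]]$times
    expect_equal(command_drive_at(cmd, tr[1]),
                 command_drive_at(cmd, tr[length(tr)]),
                 tolerance = 1e-9)
    expect_equal(sim$truth$t_rec[i] + sim$truth$t_derec[i], 20,
                 tolerance = 1e-9) # mirror about the peak at t = 10
  }
})

test_that("strong hysteresis on the sombrero produces a cap unit", {
  # theta = 15, effective offset 6: derecruitment needs drive < 9, which the
  # 10% plateau never provides, so the unit discharges to the command end
  cfg <- pool_config(n_units = 1, threshold_range = c(14.999, 15),
                     hysteresis = 6, isi_cv = 0, seed = 1)
  cmd <- generate_command("sombrero", 10, 30, 3, 10)
  sim <- simulate_pool(cfg, cmd)
  expect_true(sim$truth$censored[1])
  expect_equal(sim$truth$category[1], "cap")
  expect_equal(max(sim$trains[[1]]$times), max(cmd$t))
})

test_that("units above the drive range return empty trains, not errors", {
  cfg <- pool_config(n_units = 3, threshold_range = c(35, 60), seed = 1)
  cmd <- generate_command("ramp", 0, 30, 3)
  sim <- simulate_pool(cfg, cmd)
  expect_true(all(lengths(lapply(sim$trains, `[[`, "times")) == 0))
  expect_true(all(is.na(sim$truth$t_rec)))
})

test_that("identical config and seed reproduce spike trains exactly", {
  cfg <- pool_config(n_units = 8, seed = 42)
  cmd <- generate_command("sombrero", 10, 30, 3, 10)
  s1 <- simulate_pool(cfg, cmd)
  s2 <- simulate_pool(cfg, cmd)
  expect_identical(lapply(s1$trains, `[[`, "times"),
                   lapply(s2$trains, `[[`, "times"))
})

test_that("derecruitment time and true delta-F are monotone in hysteresis", {
  cmd <- generate_command("ramp", 0, 30, 3)
  derecs <- vapply(c(0, 1, 2, 4), function(h) {
    cfg <- pool_config(n_units = 3, threshold_range = c(10, 20),
                       hysteresis = h, isi_cv = 0, seed = 1)
    simulate_pool(cfg, cmd)$truth$t_derec[2]
  }, numeric(1))
  expect_true(all(diff(derecs) > 0))
  dfs <- vapply(c(0, 1, 2, 4), function(h) {
    cfg <- pool_config(n_units = 3, threshold_range = c(10, 20),
                       hysteresis = h, isi_cv = 0, seed = 1)
    true_delta_f(simulate_pool(cfg, cmd)$truth, "u2", "u1")
  }, numeric(1))
  expect_true(all(diff(dfs) > 0))
})

test_that("ground-truth delta-F equals the reporter-rate readout", {
  # reporter gain 1.5, test effective hysteresis 2 -> true deltaF = 3.0
  cfg <- pool_config(n_units = 2, threshold_range = c(5, 15), gain = 1.5,
                     hysteresis = c(0, 2), isi_cv = 0, seed = 1)
  cmd <- generate_command("ramp", 0, 30, 3)
  sim <- simulate_pool(cfg, cmd)
  expect_equal(true_delta_f(sim$truth, "u2", "u1"), 3.0)
  # brute force: reporter model rate at the test unit's true landmarks
  rep_rate <- function(tt) {
    cfg$rate_min + cfg$gain[1] *
      (command_drive_at(cmd, tt) + 0 - cfg$thresholds[1])
  }
  expect_equal(rep_rate(sim$truth$t_rec[2]) - rep_rate(sim$truth$t_derec[2]),
               3.0, tolerance = 1e-9)
})

test_that("spike ISI variability tracks the configured CV", {
  cfg <- pool_config(n_units = 1, threshold_range = c(4.999, 5),
                     hysteresis = 0, isi_cv = 0.2, gain = 1, seed = 11)
  cmd <- generate_command("hold", 20, 20, 3, 30)
  sim <- simulate_pool(cfg, cmd)
  isi <- diff(sim$trains[[1]]$times)
  isi <- isi[-length(isi)] # drop the terminal boundary interval
  expect_equal(stats::sd(isi) / mean(isi), 0.2, tolerance = 0.05)
  expect_equal(1 / mean(isi), cfg$rate_min + 1 * (20 - 5), tolerance = 0.02)
})

test_that("cap count is monotone nondecreasing in length_factor", {
  cmd <- generate_command("sombrero", 10, 30, 3, 10)
  n_caps <- function(lf, seed) {
    set.seed(seed)
    cfg <- pool_config(n_units = 12, hysteresis = stats::runif(12, 0, 4),
                       length_factor = lf, isi_cv = 0, seed = seed)
    sum(simulate_pool(cfg, cmd)$truth$category == "cap", na.rm = TRUE)
  }
  for (s in 1:5) expect_gte(n_caps(1.5, s), n_caps(1, s))
  expect_gt(mean(vapply(1:5, function(s) n_caps(1.5, s), numeric(1))),
            mean(vapply(1:5, function(s) n_caps(1, s), numeric(1))))
})

test_that("twitch summation peaks at Tc and superposes linearly", {
  cmd <- generate_command("hold", 10, 10, 3, 5)
  truth <- data.frame(unit_id = "u1", twitch_peak = 2, twitch_tc = 0.05,
                      threshold = 5, eff_hysteresis = 0, gain = 1)
  tr1 <- list(spike_train(3, unit_id = "u1"))
  tq <- synthesize_torque(tr1, truth, cmd, noise_sd = 0, scale = "calibrate")
  i_peak <- which.max(tq$torque_raw)
  expect_equal(tq$t[i_peak], 3 + 0.05, tolerance = 2 / 2048)
  expect_equal(max(tq$torque_raw), 2, tolerance = 1e-3)
  # two spikes far apart: same peak, twice the integral
  tr2 <- list(spike_train(c(3, 6), unit_id = "u1"))
  tq2 <- synthesize_torque(tr2, truth, cmd, noise_sd = 0, scale = "calibrate")
  expect_equal(max(tq2$torque_raw), 2, tolerance = 1e-3)
  expect_equal(sum(tq2$torque_raw) / 2048 / (sum(tq$torque_raw) / 2048), 2,
               tolerance = 1e-3)
})

test_that("noiseless torque integral equals spikes times twitch integral", {
  cfg <- pool_config(n_units = 4, isi_cv = 0, seed = 5,
                     threshold_range = c(2, 8))
  cmd <- generate_command("hold", 10, 10, 3, 3)
  sim <- simulate_pool(cfg, cmd)
  # pad: twitches near the record end are truncated, so compare against the
  # analytic integral for spikes well inside the record
  keep <- lapply(sim$trains, function(tr) {
    spike_train(tr$times[tr$times < max(cmd$t) - 1], tr$unit_id)
  })
  tq <- synthesize_torque(keep, sim$truth, cmd, noise_sd = 0,
                          scale = "calibrate")
  expected <- sum(vapply(seq_along(keep), function(i) {
    length(keep[[i]]$times) * sim$truth$twitch_peak[i] * exp(1) *
      sim$truth$twitch_tc[i]
  }, numeric(1)))
  expect_equal(sum(tq$torque_raw) / 2048, expected, tolerance = 0.01)
})

test_that("empty spike set yields an identically zero trace", {
  cmd <- generate_command("hold", 10, 10, 3, 2)
  truth <- data.frame(unit_id = "u1", twitch_peak = 2, twitch_tc = 0.05,
                      threshold = 5, eff_hysteresis = 0, gain = 1)
  tq <- synthesize_torque(list(spike_train(numeric(0), "u1")), truth, cmd,
                          noise_sd = 0, scale = "calibrate")
  expect_true(all(tq$torque_raw == 0))
})
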