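test_that("landmarks read first/last discharge and the matching torque", {
  cmd <- generate_command("ramp", 0, 30, 3)
  tr <- trace_from_command(cmd)
  # unit recruited when the noiseless 3%/s ramp reaches 15% -> t_rec = 5 s
  train <- regular_train(10, 5, 15, unit_id = "u1")
  lm <- landmarks(train, tr)
  expect_equal(lm$t_rec, 5)
  expect_equal(lm$tq_rec, 15, tolerance = 1e-3)
  expect_equal(lm$t_derec, 15)
  expect_equal(lm$tq_derec, 15, tolerance = 1e-3)
  # single-spike train: recruitment and derecruitment coincide
  lm1 <- landmarks(spike_train(7, "u2"), tr)
  expect_equal(lm1$t_rec, lm1$t_derec)
  expect_error(landmarks(spike_train(25, "u3"), tr), "cover")
  expect_error(landmarks(spike_train(numeric(0), "u4"), tr), "empty")
})

test_that("zero-hysteresis simulated units have equal rec/derec torque", {
  cfg <- pool_config(n_units = 3, hysteresis = 0, isi_cv = 0,
                     threshold_range = c(8, 20), seed = 2)
  cmd <- generate_command("ramp", 0, 30, 3)
  sim <- simulate_pool(cfg, cmd)
  tr <- trace_from_command(cmd)
  for (train in sim$trains) {
    lm <- landmarks(train, tr)
    expect_equal(lm$tq_rec, lm$tq_derec, tolerance = 0.02)
  }
})

test_that("rate-rate r2 is 1 for affine pairs, undefined for constants", {
  t <- seq(0, 10, by = 1 / 256)
  test_sm <- make_smooth(t, 10 + sin(t), "test")
  expect_equal(rate_rate_r2(test_sm, make_smooth(t, 3 + 2 * (10 + sin(t)))),
               1, tolerance = 1e-9)
  expect_true(is.na(rate_rate_r2(test_sm, make_smooth(t, rep(12, length(t))))))
  # independent noise curves decorrelate
  set.seed(4)
  r2 <- rate_rate_r2(make_smooth(t, stats::rnorm(length(t))),
                     make_smooth(t, stats::rnorm(length(t))))
  expect_lt(r2, 0.1)
})

test_that("delta-F subtracts reporter rates at the test landmarks", {
  t <- seq(0, 20, by = 1 / 256)
  # reporter rate falls linearly 14 -> 6; test active on [8, 16]
  rep_rate <- 14 - 0.4 * t
  reporter <- make_mu(t, rep_rate, t_rec = 0, t_derec = 20, unit_id = "r1")
  tt <- t[t >= 8 & t <= 16]
  test <- make_mu(tt, 14 - 0.4 * tt, t_rec = 8, t_derec = 16,
                  unit_id = "test")
  res <- delta_f(test, list(reporter))
  expect_equal(res$pairs$delta_f, (14 - 0.4 * 8) - (14 - 0.4 * 16))
  expect_equal(res$mean_delta_f, 3.2, tolerance = 1e-9)
  expect_equal(res$n_pairs, 1)
})

test_that("each exclusion criterion is enforced with its reason", {
  t <- seq(0, 20, by = 1 / 256)
  base <- 14 - 0.4 * t
  tt <- t[t >= 8 & t <= 16]
  test <- make_mu(tt, 14 - 0.4 * tt, t_rec = 8, t_derec = 16, "test")
  # (a) common-drive screen: reporter uncorrelated with the test unit
  set.seed(9)
  wiggly <- make_mu(t, 10 + sin(5 * t) + 2 * cos(2.3 * t), 0, 20, "rA")
  res_a <- delta_f(test, list(wiggly))
  expect_equal(res_a$pairs$excluded_reason, "low_r2")
  # (b) recruitment time difference below 1 s
  late <- make_mu(t[t >= 7.5], base[t >= 7.5], 7.5, 20, "rB")
  res_b <- delta_f(test, list(late))
  expect_equal(res_b$pairs$excluded_reason, "rec_time_diff")
  # (c) reporter discharge range below 0.5 pps while the test is active
  flatish <- make_mu(t, 12 - 0.015 * t, 0, 20, "rC")
  res_c <- delta_f(test, list(flatish))
  expect_equal(res_c$pairs$excluded_reason, "reporter_range")
  # all three excluded -> mean undefined
  res_all <- delta_f(test, list(wiggly, late, flatish))
  expect_true(is.na(res_all$mean_delta_f))
  expect_equal(res_all$n_pairs, 0)
})

test_that("reporters not covering both landmarks are ineligible", {
  t <- seq(0, 20, by = 1 / 256)
  tt <- t[t >= 8 & t <= 16]
  test <- make_mu(tt, 14 - 0.4 * tt, 8, 16, "test")
  short_rep <- make_mu(t[t <= 12], 14 - 0.4 * t[t <= 12], 0, 12, "rShort")
  res <- delta_f(test, list(short_rep))
  expect_equal(nrow(res$pairs), 0)
  expect_true(is.na(res$mean_delta_f))
})

test_that("surviving-pair means are permutation invariant", {
  t <- seq(0, 20, by = 1 / 256)
  tt <- t[t >= 8 & t <= 16]
  test <- make_mu(tt, 14 - 0.4 * tt, 8, 16, "test")
  reps <- list(
    make_mu(t, 14 - 0.4 * t, 0, 20, "r1"),
    make_mu(t, 16 - 0.5 * t, 1, 20, "r2"),
    make_mu(t, 12 - 0.3 * t, 2, 20, "r3"),
    make_mu(t, 12 - 0.015 * t, 0, 20, "rExcl"))
  res1 <- delta_f(test, reps)
  for (perm in list(c(2, 1, 4, 3), c(4, 3, 2, 1), c(3, 1, 2, 4))) {
    res_p <- delta_f(test, reps[perm])
    expect_equal(res_p$mean_delta_f, res1$mean_delta_f)
    expect_equal(res_p$n_pairs, res1$n_pairs)
    expect_setequal(
      res_p$pairs$reporter_id[is.na(res_p$pairs$excluded_reason)],
      res1$pairs$reporter_id[is.na(res1$pairs$excluded_reason)])
  }
})

test_that("descending metrics follow the signed arithmetic", {
  # torque peaks at t = 10; unit discharges 4 -> 17 s
  t <- seq(0, 20, by = 1 / 256)
  tq <- 30 - abs(t - 10)
  trace <- torque_trace(t, tq, mvt = 100, fs = 256, filter = FALSE)
  lm <- landmarks(regular_train(10, 4, 17, "u"), trace)
  dm <- descending_metrics(lm, trace)
  expect_equal(dm$ascend_dur, 6)
  expect_equal(dm$descend_dur, 7)
  expect_equal(dm$adr, (6 - 7) / 13, tolerance = 1e-9)
  # derecruited exactly at peak torque -> descending duration 0
  lm0 <- landmarks(regular_train(10, 4, 10, "u"), trace)
  expect_equal(descending_metrics(lm0, trace)$descend_dur, 0,
               tolerance = 1 / 256)
})
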