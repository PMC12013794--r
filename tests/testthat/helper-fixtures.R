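# Shared fixtures: all synthetic, generated in code. (regular_train comes
# from the package itself.)

# A torque trace whose %MVT equals the command drive exactly (no twitch
# dynamics, no filtering) — used where analytic torque landmarks are needed.
trace_from_command <- function(cmd, mvt = 40) {
  command_torque(cmd, mvt = mvt)
}

# Build a smoothed_rate object directly from an analytic curve.
make_smooth <- function(t, rate, unit_id = "u") {
  structure(list(t = t, rate = rate, unit_id = unit_id, method = "analytic",
                 model_params = list()),
            class = "smoothed_rate")
}

# Minimal mu record (sm + lm) from analytic pieces, for delta-F tests.
make_mu <- function(t, rate, t_rec, t_derec, unit_id = "u") {
  sm <- make_smooth(t, rate, unit_id)
  lm <- structure(list(t_rec = t_rec, t_derec = t_derec,
                       tq_rec = NA_real_, tq_derec = NA_real_,
                       rate_rec = rate[1], rate_peak = max(rate),
                       rate_derec = rate[length(rate)], unit_id = unit_id),
                  class = "mu_landmarks")
  list(sm = sm, lm = lm)
}
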