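# Simulation experiment drivers. These fix the study conditions (pool sizes,
# noise levels, hysteresis settings) used by the validation suite and the
# reproduction script; the methods vignette documents the choices.

# Evenly spaced spike train at a constant rate.
regular_train <- function(rate, from, to, unit_id = "u") {
  spike_train(seq(from, to, by = 1 / rate), unit_id = unit_id)
}

#' Delta-F parameter-recovery experiment
#'
#' Simulates triangular-ramp contractions of a 20-unit pool in which every
#' unit has gain 1.5 pps/%MVT and hysteresis `hysteresis` %MVT, so the
#' ground-truth delta-F of every test/reporter pair is
#' `1.5 * hysteresis * length_factor` pps. Each seed is analyzed blind with
#' the full pipeline (SVR smoothing, landmark detection, exclusion criteria)
#' and the mean estimated delta-F across eligible test units is collected.
#' Units without a derecruitment instant before the command end are excluded
#' (delta-F is undefined for them).
#'
#' @param n_seeds number of simulated trials.
#' @param hysteresis programmed PIC hysteresis in %MVT (default 2, i.e. true
#'   delta-F 3.0 pps; use 0 for the null/bias condition).
#' @param isi_cv ISI variability (default 0.1).
#' @param n_units pool size (default 20).
#' @param length_factor muscle-length scaling (default 1).
#' @param seed base seed; trial seeds are `seed + 1:n_seeds`.
#' @return list with `true_delta_f`, `per_seed` (mean estimate per trial),
#'   `mean_estimate`, `bias`.
#' @export
run_delta_f_recovery <- function(n_seeds = 30, hysteresis = 2, isi_cv = 0.1,
                                 n_units = 20, length_factor = 1, seed = 1) {
  cmd <- generate_command("ramp", 0, 30, 3)
  trace <- command_torque(cmd)
  truth_df <- 1.5 * hysteresis * length_factor
  per_seed <- vapply(seq_len(n_seeds), function(k) {
    cfg <- pool_config(n_units = n_units, threshold_range = c(1, 25),
                       gain = 1.5, hysteresis = hysteresis,
                       isi_cv = isi_cv, length_factor = length_factor,
                       seed = seed + k)
    sim <- simulate_pool(cfg, cmd)
    eligible <- sim$truth$unit_id[!sim$truth$censored &
                                    !is.na(sim$truth$t_rec)]
    res <- analyze_trial(sim$trains, trace, cmd = NULL)
    m <- res$metrics
    vals <- m$mean_delta_f[m$unit_id %in% eligible & m$n_pairs > 0]
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  mean_est <- mean(per_seed, na.rm = TRUE)
  list(true_delta_f = truth_df, per_seed = per_seed,
       mean_estimate = mean_est, bias = mean_est - truth_df)
}

#' Noiseless sombrero classification-recovery experiment
#'
#' Runs noiseless (deterministic-ISI, noise-free) sombrero simulations with
#' per-unit hysteresis drawn uniformly on \[0, 4\] %MVT and compares the
#' pipeline's brim/button/cap labels against the simulator's ground truth.
#'
#' @param n_seeds number of simulated trials (default 20).
#' @param n_units pool size (default 15).
#' @param seed base seed.
#' @return list with `accuracy` (fraction of units labelled identically,
#'   pooled over seeds), `n_units_checked`.
#' @export
run_classification_recovery <- function(n_seeds = 20, n_units = 15,
                                        seed = 1) {
  cmd <- generate_command("sombrero", 10, 30, 3, 10)
  win <- segment_plateaus(cmd)
  n_ok <- 0L; n_tot <- 0L
  for (k in seq_len(n_seeds)) {
    set.seed(seed + k)
    cfg <- pool_config(n_units = n_units,
                       hysteresis = stats::runif(n_units, 0, 4),
                       isi_cv = 0, seed = seed + k)
    sim <- simulate_pool(cfg, cmd)
    nonempty <- lengths(lapply(sim$trains, `[[`, "times")) > 0
    cats <- classify_units(sim$trains[nonempty], win)
    n_ok <- n_ok + sum(cats$category == sim$truth$category[nonempty])
    n_tot <- n_tot + sum(nonempty)
  }
  list(accuracy = n_ok / n_tot, n_units_checked = n_tot)
}

#' Sustained-discharge correctness experiment
#'
#' Checks the sustained-duration estimator against the analytic event-time
#' oracle on noiseless sombrero pools: zero-hysteresis units must sustain for
#' 0 s, and cap units for exactly the interval between the descending
#' recruitment-torque crossing and the command end.
#'
#' @param seed base seed.
#' @return list with `max_abs_err_zero` (s), `max_abs_err_cap` (s),
#'   `n_zero`, `n_cap`.
#' @export
run_sustained_correctness <- function(seed = 1) {
  cmd <- generate_command("sombrero", 10, 30, 3, 10)
  win <- segment_plateaus(cmd)
  pk <- command_peak(cmd)

  cfg0 <- pool_config(n_units = 6, hysteresis = 0, isi_cv = 0,
                      threshold_range = c(12, 28), seed = seed)
  sim0 <- simulate_pool(cfg0, cmd)
  errs0 <- vapply(sim0$trains, function(tr) {
    sustained_duration(tr, windows = win, cmd = cmd)$sustained_dur
  }, numeric(1))

  cfg1 <- pool_config(n_units = 6, hysteresis = 8, isi_cv = 0,
                      threshold_range = c(12, 16), seed = seed)
  sim1 <- simulate_pool(cfg1, cmd)
  stopifnot(all(sim1$truth$category == "cap"))
  errs1 <- vapply(seq_along(sim1$trains), function(i) {
    est <- sustained_duration(sim1$trains[[i]], windows = win,
                              cmd = cmd)$sustained_dur
    theta <- cfg1$thresholds[i]
    # oracle: recruited at theta on the ascent; the command re-crosses theta
    # at peak_time + (30 - theta)/3; discharge runs to the command end
    oracle <- max(cmd$t) - (pk$t + (30 - theta) / 3)
    est - oracle
  }, numeric(1))
  list(max_abs_err_zero = max(abs(errs0)), max_abs_err_cap = max(abs(errs1)),
       n_zero = length(errs0), n_cap = length(errs1))
}

#' Cross-trial MUAP matching-fidelity experiment
#'
#' Synthesizes `n_trials` EMG records of the same `n_units` units (shared
#' spatial centres, trial-specific noise at `snr_db`), re-estimates each
#' trial's templates by spike-triggered averaging, matches units across every
#' trial pair and scores recall (true pairs recovered above threshold) and
#' false merges between units whose spatial centres are at least
#' `far_dist` electrodes apart.
#'
#' @param n_trials number of trials (default 3).
#' @param n_units number of units (default 15).
#' @param snr_db EMG signal-to-noise ratio in dB (default 15).
#' @param duration record duration in s (default 20).
#' @param far_dist electrode distance defining "clearly distinct" units.
#' @param seed base seed.
#' @return list with `recall`, `n_true_pairs`, `false_merges_far`,
#'   `self_corr` (template self-correlation).
#' @export
run_matching_fidelity <- function(n_trials = 3, n_units = 15, snr_db = 15,
                                  duration = 20, far_dist = 6, seed = 1) {
  set.seed(seed)
  grid <- c(13, 5)
  centers <- cbind(sample(2:(grid[1] - 1), n_units, replace = TRUE),
                   sample(seq_len(grid[2]), n_units, replace = TRUE))
  trials <- lapply(seq_len(n_trials), function(tr) {
    trains <- lapply(seq_len(n_units), function(i) {
      rate <- 8 + (i %% 7)
      regular_train(rate, 0.5 + 0.013 * i, duration - 0.5,
                    unit_id = paste0("u", i))
    })
    syn <- synthesize_muaps_and_emg(trains, duration, grid = grid,
                                    snr_db = snr_db, seed = seed + 100 * tr,
                                    centers = centers)
    lapply(seq_len(n_units), function(i) {
      spike_triggered_average(syn$emg, trains[[i]], grid = grid)
    })
  })
  pair_tabs <- list()
  for (a in seq_len(n_trials - 1)) {
    for (b in (a + 1):n_trials) {
      pair_tabs[[length(pair_tabs) + 1]] <- cross_trial_correlations(
        trials[[a]], trials[[b]], paste0("T", a), paste0("T", b))
    }
  }
  pairs <- do.call(rbind, pair_tabs)
  res <- assign_matches(pairs)
  m <- res$matched
  true_hit <- sum(m$unit_a == m$unit_b)
  n_true <- n_units * length(pair_tabs)
  dist_of <- function(ua, ub) {
    ia <- as.integer(sub("u", "", ua)); ib <- as.integer(sub("u", "", ub))
    sqrt(sum((centers[ia, ] - centers[ib, ])^2))
  }
  wrong <- m[m$unit_a != m$unit_b, , drop = FALSE]
  false_far <- if (nrow(wrong)) sum(mapply(dist_of, wrong$unit_a,
                                           wrong$unit_b) >= far_dist) else 0L
  self_corr <- xcorr2_normalized(trials[[1]][[1]], trials[[1]][[1]])
  list(recall = true_hit / n_true, n_true_pairs = n_true,
       false_merges_far = false_far, self_corr = self_corr)
}

#' Muscle-length (hysteresis-scaling) direction-of-effect experiment
#'
#' Compares PIC prolongation metrics between long (`lf_long`) and short
#' (`lf_short`) muscle-length conditions on matched seeds: estimated delta-F
#' on triangular ramps, descending duration, cap counts and the proportion
#' of ramp-recruited units sustaining discharge more than 2 s on sombreros,
#' and the plateau torque-CV change of sombrero versus hold contractions.
#'
#' @param n_seeds seeds per condition (default 20).
#' @param lf_long,lf_short length factors (defaults 0.7 and 1.5).
#' @param n_units pool size (default 15).
#' @param delta_f_seeds seeds for the (slower) delta-F arm (default
#'   `min(n_seeds, 12)`).
#' @param seed base seed.
#' @return list of per-condition seed-mean metrics: `delta_f_long/short`,
#'   `descend_long/short`, `caps_long/short`, `prop_long/short`,
#'   `dcv_sombrero`, `dcv_hold` (each a per-seed vector).
#' @export
run_length_effects <- function(n_seeds = 20, lf_long = 0.7, lf_short = 1.5,
                               n_units = 15, delta_f_seeds = min(n_seeds, 12),
                               seed = 1) {
  smb <- generate_command("sombrero", 10, 30, 3, 10)
  hold <- generate_command("hold", 10, 30, 3, 10)
  rmp <- generate_command("ramp", 0, 30, 3)
  win <- segment_plateaus(smb)

  sombrero_arm <- function(lf, s) {
    set.seed(s)
    cfg <- pool_config(n_units = n_units,
                       hysteresis = stats::runif(n_units, 0, 4),
                       isi_cv = 0.15, length_factor = lf, seed = s)
    sim <- simulate_pool(cfg, smb, renormalize_plateau2 = TRUE)
    nonempty <- lengths(lapply(sim$trains, `[[`, "times")) > 3
    cats <- classify_units(sim$trains[nonempty], win)
    sus <- lapply(sim$trains[nonempty][cats$category == "cap"], function(tr)
      sustained_duration(tr, windows = win, cmd = smb))
    prop <- suppressWarnings(proportion_sustained(cats, sus))
    trace <- synthesize_torque(sim$trains, sim$truth, smb, seed = s)
    list(n_cap = sum(cats$category == "cap"), prop = prop,
         dcv = delta_cv(trace, win))
  }
  hold_arm <- function(lf, s) {
    set.seed(s)
    cfg <- pool_config(n_units = n_units,
                       hysteresis = stats::runif(n_units, 0, 4),
                       isi_cv = 0.15, length_factor = lf, seed = s)
    sim <- simulate_pool(cfg, hold)
    trace <- synthesize_torque(sim$trains, sim$truth, hold, seed = s + 5000)
    delta_cv(trace, win)
  }
  ramp_arm <- function(lf, s) {
    set.seed(s)
    cfg <- pool_config(n_units = n_units, gain = 1.5,
                       hysteresis = stats::runif(n_units, 1, 3),
                       isi_cv = 0.1, length_factor = lf, seed = s)
    sim <- simulate_pool(cfg, rmp)
    trace <- command_torque(rmp)
    eligible <- sim$truth$unit_id[!sim$truth$censored &
                                    !is.na(sim$truth$t_rec)]
    res <- analyze_trial(sim$trains, trace, cmd = NULL)
    m <- res$metrics
    list(delta_f = mean(m$mean_delta_f[m$unit_id %in% eligible &
                                         m$n_pairs > 0], na.rm = TRUE),
         descend = mean(m$descend_dur[m$unit_id %in% eligible]))
  }
  descend_arm <- function(lf, s) {
    set.seed(s)
    cfg <- pool_config(n_units = n_units,
                       hysteresis = stats::runif(n_units, 1, 3),
                       isi_cv = 0.15, length_factor = lf, seed = s)
    sim <- simulate_pool(cfg, rmp)
    trace <- command_torque(rmp)
    res <- analyze_trial(sim$trains, trace, cmd = NULL, smooth = FALSE)
    mean(res$metrics$descend_dur, na.rm = TRUE)
  }

  seeds <- seed + seq_len(n_seeds)
  df_seeds <- seed + seq_len(delta_f_seeds)
  smb_long <- lapply(seeds, function(s) sombrero_arm(lf_long, s))
  smb_short <- lapply(seeds, function(s) sombrero_arm(lf_short, s))
  df_long <- vapply(df_seeds, function(s) ramp_arm(lf_long, s)$delta_f,
                    numeric(1))
  df_short <- vapply(df_seeds, function(s) ramp_arm(lf_short, s)$delta_f,
                     numeric(1))
  list(
    delta_f_long = df_long, delta_f_short = df_short,
    descend_long = vapply(seeds, function(s) descend_arm(lf_long, s),
                          numeric(1)),
    descend_short = vapply(seeds, function(s) descend_arm(lf_short, s),
                           numeric(1)),
    caps_long = vapply(smb_long, `[[`, numeric(1), "n_cap"),
    caps_short = vapply(smb_short, `[[`, numeric(1), "n_cap"),
    prop_long = vapply(smb_long, `[[`, numeric(1), "prop"),
    prop_short = vapply(smb_short, `[[`, numeric(1), "prop"),
    dcv_sombrero = vapply(smb_long, `[[`, numeric(1), "dcv"),
    dcv_sombrero_short = vapply(smb_short, `[[`, numeric(1), "dcv"),
    dcv_hold = vapply(seeds, function(s) hold_arm(lf_long, s), numeric(1)),
    dcv_hold_short = vapply(seeds, function(s) hold_arm(lf_short, s),
                            numeric(1))
  )
}

#' Mixed-model calibration experiment (coverage and type-I error)
#'
#' Replicated fits of the plateau-effect mixed model on synthetic tables
#' with a known participant-random-intercept structure: with a true plateau
#' effect, scores 95% Wald-CI coverage of the effect; with no effect, scores
#' the likelihood-ratio rejection rate at alpha = 0.05.
#'
#' @param n_rep_coverage replicates for the coverage arm (default 50).
#' @param n_rep_null replicates for the type-I arm (default 200).
#' @param effect true plateau effect in pps (default -2).
#' @param n_part participants (default 12).
#' @param part_sd participant random-intercept SD (default 0.5).
#' @param seed base seed.
#' @return list with `coverage`, `type1_rate`, and the replicate counts.
#' @export
run_lmm_calibration <- function(n_rep_coverage = 50, n_rep_null = 200,
                                effect = -2, n_part = 12, part_sd = 0.5,
                                seed = 1) {
  sim_table <- function(eff, s) {
    set.seed(s)
    grid <- expand.grid(participant = paste0("p", seq_len(n_part)),
                        trial = 1:4, plateau = c("one", "two"))
    b <- stats::rnorm(n_part, sd = part_sd)
    grid$rate <- 10 + ifelse(grid$plateau == "two", eff, 0) +
      b[as.integer(factor(grid$participant))] + stats::rnorm(nrow(grid))
    grid
  }
  covered <- vapply(seq_len(n_rep_coverage), function(k) {
    fit <- suppressMessages(
      fit_mixed_model(sim_table(effect, seed + k), "rate", "plateau",
                      covariate = "trial", marginal_means = FALSE))
    eff_row <- fit$effects[fit$effects$term == "plateautwo", ]
    !is.na(eff_row$ci_lo) && eff_row$ci_lo <= effect &&
      effect <= eff_row$ci_hi
  }, logical(1))
  rejected <- vapply(seq_len(n_rep_null), function(k) {
    fit <- suppressWarnings(suppressMessages(
      fit_mixed_model(sim_table(0, seed + 10000 + k), "rate", "plateau",
                      covariate = "trial", marginal_means = FALSE)))
    fit$lrt$p[1] < 0.05
  }, logical(1))
  list(coverage = mean(covered), type1_rate = mean(rejected),
       n_rep_coverage = n_rep_coverage, n_rep_null = n_rep_null)
}

#' Configuration for the plateau drive-perturbation probe
#'
#' A pool in the strong-PIC (short-muscle) regime with a near-uniform
#' threshold spread, so that units recruited during the ramp and retained by
#' their PIC hysteresis (cap units) outnumber the plateau-one (brim) units.
#' Used with [plateau_response_ratio()].
#'
#' @param seed integer seed.
#' @return a [pool_config()].
#' @export
perturbation_pool_config <- function(seed = 1) {
  pool_config(n_units = 20, threshold_range = c(5, 28), threshold_shape = 0,
              hysteresis = 5, length_factor = 1.6, isi_cv = 0, seed = seed)
}
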