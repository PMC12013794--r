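#' Configure a simulated motoneuron pool
#'
#' Defines a pool of motor units with recruitment thresholds skewed toward low
#' values, per-unit discharge gains, and a programmable drive-domain
#' recruitment/derecruitment hysteresis that stands in for the persistent
#' inward current (PIC): a unit is recruited when the descending drive reaches
#' its threshold and, once recruited, behaves as if it received an extra
#' depolarizing offset, so it is derecruited only when the drive falls below
#' threshold minus that offset.
#'
#' @param n_units number of motor units.
#' @param threshold_range length-2 numeric, min/max recruitment threshold in
#'   %MVT.
#' @param threshold_shape exponent `a` of the threshold spacing
#'   `theta_i = min + (max - min) * (exp(a i/n) - 1)/(exp(a) - 1)`; larger
#'   values skew thresholds toward low %MVT (many low-threshold units), 0
#'   gives a uniform spread.
#' @param rate_min discharge rate at recruitment, pulses per second (pps).
#' @param gain discharge gain in pps per %MVT of effective drive; scalar or
#'   per-unit vector.
#' @param hysteresis PIC hysteresis offset per unit in %MVT (scalar recycled
#'   or per-unit vector); the effective offset is `hysteresis * length_factor`.
#' @param isi_cv coefficient of variation of inter-spike intervals (0 gives
#'   deterministic ISIs); must lie in \[0, 0.5\].
#' @param length_factor dimensionless scaling of the hysteresis encoding
#'   muscle length: short muscle > 1 (excitable, strong PIC), long muscle < 1.
#' @param seed integer seed making the pool realization reproducible.
#' @param twitch_peak_range length-2 range of twitch peak amplitudes
#'   (arbitrary units); assigned geometrically so high-threshold units have
#'   the largest twitches (size principle).
#' @param twitch_tc_range length-2 range of twitch contraction times in
#'   seconds, assigned from slow (low-threshold) to fast (high-threshold).
#' @return object of class `pool_config`.
#' @export
pool_config <- function(n_units = 20,
                        threshold_range = c(1, 28),
                        threshold_shape = 3,
                        rate_min = 8,
                        gain = 1.5,
                        hysteresis = 2,
                        isi_cv = 0.15,
                        length_factor = 1,
                        seed = 1L,
                        twitch_peak_range = c(1, 25),
                        twitch_tc_range = c(0.09, 0.03)) {
  stopifnot(n_units >= 1, length(threshold_range) == 2,
            diff(threshold_range) > 0)
  if (isi_cv < 0 || isi_cv > 0.5)
    stop("`isi_cv` must lie in [0, 0.5]")
  if (length_factor <= 0) stop("`length_factor` must be positive")
  gain <- rep_len(gain, n_units)
  hysteresis <- rep_len(hysteresis, n_units)
  if (any(hysteresis < 0)) stop("`hysteresis` must be nonnegative")

  i <- seq_len(n_units)
  a <- threshold_shape
  frac <- if (abs(a) < 1e-12) i / n_units else
    (exp(a * i / n_units) - 1) / (exp(a) - 1)
  thresholds <- threshold_range[1] + diff(threshold_range) * frac

  # size principle: twitch amplitude grows geometrically with threshold rank,
  # contraction time shrinks
  p <- exp(seq(log(twitch_peak_range[1]), log(twitch_peak_range[2]),
               length.out = n_units))
  tc <- seq(twitch_tc_range[1], twitch_tc_range[2], length.out = n_units)

  structure(
    list(n_units = n_units, thresholds = thresholds,
         threshold_range = threshold_range, threshold_shape = threshold_shape,
         rate_min = rate_min, gain = gain, hysteresis = hysteresis,
         isi_cv = isi_cv, length_factor = length_factor,
         seed = as.integer(seed),
         twitch_peak = p, twitch_tc = tc),
    class = "pool_config"
  )
}

#' @export
print.pool_config <- function(x, ...) {
  cat(sprintf(
    "<pool_config> %d units, thresholds %.1f-%.1f %%MVT (shape %g)\n",
    x$n_units, min(x$thresholds), max(x$thresholds), x$threshold_shape))
  cat(sprintf("  rate_min %g pps, gain %g-%g pps/%%MVT, hysteresis %g-%g %%MVT\n",
              x$rate_min, min(x$gain), max(x$gain),
              min(x$hysteresis), max(x$hysteresis)))
  cat(sprintf("  isi_cv %g, length_factor %g, seed %d\n",
              x$isi_cv, x$length_factor, x$seed))
  invisible(x)
}

#' Construct a spike train object
#'
#' @param times numeric vector of strictly increasing discharge times (s).
#' @param unit_id unit identifier.
#' @param trial_id trial identifier.
#' @return object of class `spike_train`.
#' @export
spike_train <- function(times, unit_id = NA, trial_id = NA) {
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("spike times must be strictly increasing")
  structure(list(times = times, unit_id = unit_id, trial_id = trial_id),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit %s, %d spikes", x$unit_id, length(x$times)))
  if (length(x$times)) cat(sprintf(" over [%.3f, %.3f] s", min(x$times),
                                   max(x$times)))
  cat("\n")
  invisible(x)
}

# Per-unit instantaneous model rate while active (pps). Effective drive is
# the command drive plus the PIC offset once the unit is recruited.
unit_rate_fun <- function(cfg, i, cmd, times) {
  eff <- cfg$hysteresis[i] * cfg$length_factor
  cfg$rate_min + cfg$gain[i] *
    (command_drive_at(cmd, times) + eff - cfg$thresholds[i])
}

#' Simulate a motoneuron pool driven by a command profile
#'
#' Each unit is recruited at the first instant the drive reaches its threshold
#' `theta_i`. Once recruited, the PIC hysteresis adds an effective drive
#' offset `hysteresis_i * length_factor`, so the unit is derecruited only when
#' the drive falls below `theta_i - hysteresis_i * length_factor` (or the
#' command ends). While active, the unit's mean rate is
#' `rate_min + gain_i * (drive + offset - theta_i)` and spikes are drawn by
#' time-rescaling a gamma renewal process with ISI coefficient of variation
#' `isi_cv` (`isi_cv = 0` gives deterministic ISIs). The train always contains
#' a spike at the exact recruitment instant and a terminal spike at the end of
#' the active interval, the generator's definition of first/last discharge.
#'
#' @param cfg a [pool_config()].
#' @param cmd a [generate_command()] profile.
#' @param trial_id identifier stamped on the returned trains.
#' @param renormalize_plateau2 logical; if `TRUE` (sombrero commands only),
#'   the common drive during the second plateau is reduced so that the
#'   expected noiseless pool torque matches the first plateau despite the
#'   extra cap units kept active by their PICs — emulating the compensatory
#'   reduction in descending drive needed to hold the same torque.
#' @return list with `trains` (list of [spike_train()], one per unit, possibly
#'   empty) and `truth` (a `pool_truth` data.frame of per-unit ground truth:
#'   threshold, effective hysteresis, gain, exact recruitment/derecruitment
#'   times, censoring at command end, true category where the command has
#'   plateau labels, and twitch parameters).
#' @seealso [true_delta_f()] for ground-truth pairwise delta-F values.
#' @export
simulate_pool <- function(cfg, cmd, trial_id = "trial1",
                          renormalize_plateau2 = FALSE) {
  stopifnot(inherits(cfg, "pool_config"), inherits(cmd, "command_profile"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(cfg$seed)

  cmd_use <- cmd
  if (renormalize_plateau2) cmd_use <- renormalize_plateau2_cmd(cfg, cmd)

  t_end_cmd <- max(cmd_use$t)
  n <- cfg$n_units
  lf <- cfg$length_factor
  trains <- vector("list", n)
  truth <- data.frame(
    unit_id = paste0("u", seq_len(n)),
    threshold = cfg$thresholds,
    hysteresis = cfg$hysteresis,
    eff_hysteresis = cfg$hysteresis * lf,
    gain = cfg$gain,
    t_rec = NA_real_, t_derec = NA_real_,
    censored = FALSE,
    twitch_peak = cfg$twitch_peak,
    twitch_tc = cfg$twitch_tc,
    stringsAsFactors = FALSE
  )

  for (i in seq_len(n)) {
    theta <- cfg$thresholds[i]
    eff <- cfg$hysteresis[i] * lf
    t_rec <- command_crossing(cmd_use, theta, direction = "up")
    if (is.na(t_rec)) {
      trains[[i]] <- spike_train(numeric(0), truth$unit_id[i], trial_id)
      next
    }
    t_derec <- command_crossing(cmd_use, theta - eff, after = t_rec,
                                direction = "down")
    censored <- is.na(t_derec) || t_derec > t_end_cmd
    t_end <- if (censored) t_end_cmd else t_derec
    truth$t_rec[i] <- t_rec
    truth$t_derec[i] <- t_end
    truth$censored[i] <- censored
    trains[[i]] <- draw_spikes(cfg, i, cmd_use, t_rec, t_end, trial_id,
                               truth$unit_id[i])
  }

  truth$category <- true_categories(cmd, truth)
  attr(truth, "rate_min") <- cfg$rate_min
  class(truth) <- c("pool_truth", class(truth))
  list(trains = trains, truth = truth, cfg = cfg, cmd = cmd_use,
       trial_id = trial_id)
}

# Spikes on [t_rec, t_end] via time-rescaling: the integrated rate is mapped
# through cumulative sums of gamma(shape k, rate k) increments (mean 1,
# CV = isi_cv); isi_cv = 0 uses unit increments, giving deterministic ISIs.
draw_spikes <- function(cfg, i, cmd, t_rec, t_end, trial_id, unit_id) {
  if (t_end <= t_rec) return(spike_train(t_rec, unit_id, trial_id))
  fs <- cmd$fs
  grid <- seq(t_rec, t_end, by = 1 / fs)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
  r <- pmax(unit_rate_fun(cfg, i, cmd, grid), 1e-9)
  lam <- c(0, cumsum((r[-1] + r[-length(r)]) / 2 * diff(grid)))
  lam_max <- lam[length(lam)]
  if (lam_max < 1) {
    return(spike_train(unique(c(t_rec, t_end)), unit_id, trial_id))
  }
  if (cfg$isi_cv == 0) {
    targets <- seq_len(floor(lam_max))
  } else {
    k <- 1 / cfg$isi_cv^2
    n_draw <- ceiling(lam_max + 6 * sqrt(lam_max) + 10)
    inc <- stats::rgamma(n_draw, shape = k, rate = k)
    cs <- cumsum(inc)
    while (cs[length(cs)] < lam_max) {
      inc <- stats::rgamma(n_draw, shape = k, rate = k)
      cs <- c(cs, cs[length(cs)] + cumsum(inc))
    }
    targets <- cs[cs <= lam_max]
  }
  mid <- stats::approx(lam, grid, xout = targets, ties = "ordered")$y
  times <- c(t_rec, mid)
  # terminal spike at the end of the active interval
  if (t_end - times[length(times)] > 1e-4) times <- c(times, t_end)
  times <- times[!duplicated(round(times * 1e7))]
  spike_train(times, unit_id, trial_id)
}

# Ground-truth categories from exact event times against the command's
# analytic windows (sombrero/hold only; NA otherwise).
true_categories <- function(cmd, truth) {
  labs <- cmd$segments$label
  if (!all(c("plateau_one", "ramp_up", "ramp_down", "plateau_two") %in% labs))
    return(rep(NA_character_, nrow(truth)))
  ramp_start <- cmd$segments$start[labs == "ramp_up"]
  p2_start <- cmd$segments$start[labs == "plateau_two"]
  vapply(seq_len(nrow(truth)), function(i) {
    tr <- truth$t_rec[i]
    if (is.na(tr)) return(NA_character_)
    if (tr < ramp_start) return("brim")
    if (tr >= p2_start) return("other")
    if (truth$t_derec[i] > p2_start) "cap" else "button"
  }, character(1))
}

#' Ground-truth delta-F for a test/reporter unit pair
#'
#' In the hysteresis model the reporter's rate change between the test unit's
#' recruitment and derecruitment is exactly
#' `gain_reporter * hysteresis_test * length_factor`: the drive equals
#' `theta_test` at test recruitment and `theta_test - hysteresis_test *
#' length_factor` at test derecruitment, and the reporter's own offset terms
#' cancel in the difference.
#'
#' @param truth `pool_truth` from [simulate_pool()].
#' @param test_id,reporter_id unit identifiers.
#' @return delta-F in pps, or `NA` if the test unit was never derecruited
#'   before the command end (no derecruitment instant exists).
#' @export
true_delta_f <- function(truth, test_id, reporter_id) {
  it <- match(test_id, truth$unit_id)
  ir <- match(reporter_id, truth$unit_id)
  if (is.na(it) || is.na(ir)) stop("unknown unit id")
  if (is.na(truth$t_derec[it]) || truth$censored[it]) return(NA_real_)
  truth$gain[ir] * truth$eff_hysteresis[it]
}

# Reduce the constant drive of plateau_two so that the expected noiseless
# pool torque (with hysteretically retained units) matches plateau one.
renormalize_plateau2_cmd <- function(cfg, cmd) {
  labs <- cmd$segments$label
  if (!all(c("plateau_one", "plateau_two") %in% labs)) return(cmd)
  d1 <- cmd$segments$v_start[labs == "plateau_one"]
  lf <- cfg$length_factor
  # expected steady torque at drive d for active set `act`
  steady <- function(d, act) {
    r <- cfg$rate_min + cfg$gain * (d + cfg$hysteresis * lf - cfg$thresholds)
    sum((cfg$twitch_peak * exp(1) * cfg$twitch_tc * pmax(r, 0))[act])
  }
  target <- steady(d1, cfg$thresholds <= d1)
  # units recruited by the peak retain activity while d >= theta - eff
  recruited <- cfg$thresholds <= max(cmd$segments$v_end, cmd$segments$v_start)
  f <- function(d) {
    act <- recruited & (cfg$thresholds - cfg$hysteresis * lf <= d)
    steady(d, act) - target
  }
  d2 <- tryCatch(stats::uniroot(f, c(0.2 * d1, d1))$root, error = function(e) d1)
  seg <- cmd$segments
  i2 <- which(labs == "plateau_two")
  seg$v_start[i2] <- d2
  seg$v_end[i2] <- d2
  # keep the descending ramp continuous down to the renormalized level
  idn <- which(labs == "ramp_down")
  if (length(idn)) seg$v_end[idn] <- d2
  out <- cmd
  out$segments <- seg
  out$drive <- eval_segments(seg, cmd$t)
  out
}

#' Pool discharge response ratio to matched drive perturbations
#'
#' Applies an identical brief excitatory drive pulse at the centre of plateau
#' one and (separately) plateau two of a sombrero command, and compares the
#' net change in summed discharge rate of the units already active at pulse
#' onset. With cap units kept discharging through the second plateau by their
#' PIC hysteresis, the same input engages many more units and the response in
#' plateau two is correspondingly larger. Computed deterministically from the
#' model rate functions (no spike sampling).
#'
#' @param cfg a [pool_config()]; for a meaningful probe use a pool with
#'   substantial effective hysteresis so cap units are present.
#' @param cmd a sombrero [generate_command()] profile.
#' @param pulse_amp pulse amplitude in %MVT (default 1).
#' @param pulse_dur pulse duration in seconds (default 0.5).
#' @return list with `response_plateau_one`, `response_plateau_two`
#'   (integrated extra discharge, spikes) and `ratio` (plateau two / one).
#' @export
plateau_response_ratio <- function(cfg, cmd, pulse_amp = 1, pulse_dur = 0.5) {
  labs <- cmd$segments$label
  if (!all(c("plateau_one", "plateau_two") %in% labs))
    stop("`cmd` must be a sombrero command with plateau labels")
  lf <- cfg$length_factor
  resp <- function(which_plateau) {
    s <- cmd$segments[labs == which_plateau, ]
    mid <- (s$start + s$end) / 2
    win <- c(mid - pulse_dur / 2, mid + pulse_dur / 2)
    # active set at pulse onset under the baseline command
    active <- vapply(seq_len(cfg$n_units), function(i) {
      theta <- cfg$thresholds[i]
      eff <- cfg$hysteresis[i] * lf
      t_rec <- command_crossing(cmd, theta, direction = "up")
      if (is.na(t_rec) || t_rec > win[1]) return(FALSE)
      t_derec <- command_crossing(cmd, theta - eff, after = t_rec,
                                  direction = "down")
      is.na(t_derec) || t_derec > win[1]
    }, logical(1))
    # extra discharge of those units: gain * pulse integrated over the window
    sum(cfg$gain[active]) * pulse_amp * pulse_dur
  }
  r1 <- resp("plateau_one")
  r2 <- resp("plateau_two")
  list(response_plateau_one = r1, response_plateau_two = r2,
       ratio = if (r1 > 0) r2 / r1 else NA_real_)
}
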