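#' Construct a torque trace
#'
#' Bundles a sampled torque signal with its 50 Hz low-pass filtered version
#' and the %MVT normalization used by all torque-domain metrics.
#'
#' @param t time vector in seconds (uniform grid).
#' @param torque_raw raw torque samples (Nm or arbitrary units).
#' @param mvt maximum voluntary torque in the same units as `torque_raw`.
#' @param fs sampling rate in Hz.
#' @param filter logical; apply the zero-phase fifth-order 50 Hz Butterworth
#'   low-pass to produce `torque_filt` (default `TRUE`). With `FALSE`,
#'   `torque_filt` equals `torque_raw`.
#' @return object of class `torque_trace` with fields `t`, `torque_raw`,
#'   `torque_filt`, `torque_pct` (= 100 * torque_filt / mvt), `mvt`, `fs`.
#' @export
torque_trace <- function(t, torque_raw, mvt, fs = 2048, filter = TRUE) {
  stopifnot(length(t) == length(torque_raw), mvt > 0, fs > 0)
  filt <- if (filter) filter_torque(torque_raw, fs) else torque_raw
  structure(
    list(t = t, torque_raw = torque_raw, torque_filt = filt,
         torque_pct = 100 * filt / mvt, mvt = mvt, fs = fs),
    class = "torque_trace"
  )
}

#' @export
print.torque_trace <- function(x, ...) {
  cat(sprintf("<torque_trace> %.1f s at %g Hz, MVT = %.3g, mean %.2f %%MVT\n",
              max(x$t) - min(x$t), x$fs, x$mvt, mean(x$torque_pct)))
  invisible(x)
}

#' Synthesize torque from simulated spike trains by twitch summation
#'
#' Each unit's spike train is convolved with its twitch
#' `P * (t/Tc) * exp(1 - t/Tc)` (peak `P` at lag `Tc`) and the pool output is
#' summed. Band-limited noise (white noise low-passed at 10 Hz) of standard
#' deviation `noise_sd` %MVT is added on the %MVT scale.
#'
#' @param trains list of [spike_train()] objects.
#' @param truth `pool_truth` carrying per-unit `twitch_peak` and `twitch_tc`.
#' @param cmd the command profile that produced the trains (defines the time
#'   span and, for `scale = "track"`, the %MVT normalization target).
#' @param noise_sd torque noise SD in %MVT (default 0.3; 0 for noiseless).
#' @param fs sampling rate in Hz.
#' @param scale `"track"` (default) converts summed torque to %MVT by
#'   inverting the pool's ascending steady-state drive-to-torque map, so the
#'   calibrated torque tracks the command on the ascending limb (the
#'   simulator's stand-in for the participant's tracking calibration) and
#'   PIC-retained discharge appears as torque excess on the descent;
#'   `"calibrate"` applies the linear normalization by the analytic
#'   steady-state pool output at a 100 %MVT drive.
#' @param seed optional integer seed for the noise (defaults to the
#'   truth-free RNG state).
#' @return a [torque_trace()].
#' @export
synthesize_torque <- function(trains, truth, cmd, noise_sd = 0.3, fs = 2048,
                              scale = c("track", "calibrate"), seed = NULL) {
  scale <- match.arg(scale)
  stopifnot(inherits(cmd, "command_profile"))
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
  }
  t <- seq(0, max(cmd$t), by = 1 / fs)
  if (t[length(t)] < max(cmd$t)) t <- c(t, max(cmd$t))
  n_s <- length(t)
  raw <- numeric(n_s)
  for (i in seq_along(trains)) {
    times <- trains[[i]]$times
    if (!length(times)) next
    tc <- truth$twitch_tc[i]
    p <- truth$twitch_peak[i]
    kern_t <- seq(0, 7 * tc, by = 1 / fs)
    kern <- p * (kern_t / tc) * exp(1 - kern_t / tc)
    imp <- numeric(n_s)
    idx <- pmin(pmax(round(times * fs) + 1, 1), n_s)
    for (j in idx) imp[j] <- imp[j] + 1
    raw <- raw + fft_convolve(imp, kern, n_s)
  }

  if (scale == "track") {
    # %MVT-equivalent calibration: invert the pool's ascending steady-state
    # drive -> torque map, the simulator's stand-in for the participant's
    # tracking calibration. On the ascending limb the calibrated torque
    # tracks the command; PIC-retained units then show up as torque excess
    # on the descending limb and second plateau, as in measured data.
    d_grid <- seq(0, 110, by = 0.25)
    t_map <- vapply(d_grid, function(d) steady_torque(truth, d), numeric(1))
    pct <- stats::approx(t_map, d_grid, xout = raw, rule = 2,
                         ties = min)$y
    mvt_nm <- 40 # nominal Nm scale for the physical channel
    raw <- pct * mvt_nm / 100
    mvt <- mvt_nm
  } else {
    mvt <- calibrate_mvt(truth)
  }

  if (noise_sd > 0) {
    noise <- stats::rnorm(n_s)
    bf <- signal::butter(2, 10 / (fs / 2), type = "low")
    noise <- signal::filtfilt(bf, noise)
    noise <- noise / stats::sd(noise) * noise_sd # %MVT units
    raw <- raw + noise * mvt / 100
  }
  torque_trace(t, raw, mvt = mvt, fs = fs)
}

# Expected steady-state pool torque at constant drive d on the ascending
# limb (units recruited at threshold discharge with their PIC offset).
steady_torque <- function(truth, d) {
  rate_min <- attr(truth, "rate_min") %||% 8
  act <- !is.na(truth$threshold) & truth$threshold <= d
  if (!any(act)) return(0)
  r <- rate_min + truth$gain[act] *
    (d + truth$eff_hysteresis[act] - truth$threshold[act])
  sum(truth$twitch_peak[act] * exp(1) * truth$twitch_tc[act] * pmax(r, 0))
}

# Linear convolution via FFT on a padded (highly composite) length; returns
# the first `n_out` samples of x * k.
fft_convolve <- function(x, k, n_out = length(x)) {
  n <- stats::nextn(length(x) + length(k) - 1)
  X <- stats::fft(c(x, numeric(n - length(x))))
  K <- stats::fft(c(k, numeric(n - length(k))))
  out <- Re(stats::fft(X * K, inverse = TRUE)) / n
  out[seq_len(n_out)]
}

# Analytic steady-state pool output at a 100 %MVT calibration drive:
# sum over units of twitch integral (P * e * Tc) times steady rate.
calibrate_mvt <- function(truth) {
  r <- pmax(0, truth$gain * (100 + truth$eff_hysteresis - truth$threshold)) +
    attr(truth, "rate_min") %||% 8
  sum(truth$twitch_peak * exp(1) * truth$twitch_tc * r)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Idealized torque trace tracking a command exactly
#'
#' A noiseless torque trace whose %MVT equals the command drive sample for
#' sample (no twitch dynamics, no filtering). Useful as the torque reference
#' when analytic landmark torques are wanted, e.g. for simulator-based
#' parameter-recovery studies where the command is the ground truth.
#'
#' @param cmd a [generate_command()] profile.
#' @param mvt nominal MVT in Nm (scales the raw channel only).
#' @return a [torque_trace()].
#' @export
command_torque <- function(cmd, mvt = 40) {
  stopifnot(inherits(cmd, "command_profile"))
  torque_trace(cmd$t, command_drive_at(cmd, cmd$t) * mvt / 100, mvt = mvt,
               fs = cmd$fs, filter = FALSE)
}

#' Low-pass filter a torque signal (fifth-order Butterworth, 50 Hz)
#'
#' @param raw torque samples.
#' @param fs sampling rate in Hz; must exceed twice the cutoff.
#' @param cutoff low-pass cutoff in Hz (default 50).
#' @param zero_phase logical; `TRUE` (default) applies the filter forward and
#'   backward ([signal::filtfilt()]) so landmark torques are not lag-shifted;
#'   `FALSE` gives the single-pass filter with the textbook -3 dB point at
#'   the cutoff.
#' @return filtered samples, same length as the input.
#' @export
filter_torque <- function(raw, fs, cutoff = 50, zero_phase = TRUE) {
  if (fs <= 2 * cutoff)
    stop("sampling rate must exceed twice the filter cutoff")
  bf <- signal::butter(5, cutoff / (fs / 2), type = "low")
  if (zero_phase) signal::filtfilt(bf, raw)
  else as.numeric(signal::filter(bf, raw))
}

#' Moving-average smoothing as used for visual feedback
#'
#' Centred moving average with a 125 ms window; edges are handled by window
#' truncation (the average runs over the available samples only), so a
#' constant input is reproduced exactly everywhere.
#'
#' @param raw torque samples.
#' @param fs sampling rate in Hz.
#' @param window window length in seconds (default 0.125).
#' @return smoothed samples, same length as input.
#' @export
feedback_smooth <- function(raw, fs, window = 0.125) {
  w <- round(window * fs)
  if (w < 2) stop("window must cover at least 2 samples")
  half <- floor(w / 2)
  n <- length(raw)
  cs <- cumsum(c(0, raw))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Torque coefficient of variation within a window
#'
#' CV = 100 * sd/mean of the %MVT torque within the window (sample SD), the
#' standard force-steadiness metric.
#'
#' @param trace a [torque_trace()].
#' @param window length-2 numeric `(start, end)` in seconds.
#' @return CV in percent.
#' @export
torque_cv <- function(trace, window) {
  stopifnot(inherits(trace, "torque_trace"), length(window) == 2)
  sel <- trace$t >= window[1] & trace$t <= window[2]
  if (!any(sel)) stop("window does not overlap the trace")
  x <- trace$torque_pct[sel]
  m <- mean(x)
  if (m <= 0) stop("non-positive mean torque in window (failed trial?)")
  100 * stats::sd(x) / m
}

#' Change in torque CV between the two plateaus
#'
#' CV(plateau two) - CV(plateau one), the per-trial steadiness degradation
#' metric. Windows are trimmed at both ends to avoid ramp-transition
#' transients.
#'
#' @param trace a [torque_trace()].
#' @param windows a [segment_plateaus()] result.
#' @param trim seconds trimmed from each end of each plateau (default 0.5).
#' @return delta CV in percentage points.
#' @export
delta_cv <- function(trace, windows, trim = 0.5) {
  p1 <- windows$plateau_one + c(trim, -trim)
  p2 <- windows$plateau_two + c(trim, -trim)
  torque_cv(trace, p2) - torque_cv(trace, p1)
}

#' Extract plateau and ramp windows from a command profile
#'
#' Windows are copied from the command's analytic breakpoints (never inferred
#' from torque). For hold contractions the windows equal those of the matched
#' sombrero, so plateau comparisons are time-matched across contraction
#' types.
#'
#' @param cmd a [generate_command()] profile with plateau labels.
#' @return object of class `plateau_windows`: list with `plateau_one`,
#'   `ramp`, `plateau_two`, each a length-2 numeric `(start, end)` in s.
#' @export
segment_plateaus <- function(cmd) {
  stopifnot(inherits(cmd, "command_profile"))
  labs <- cmd$segments$label
  need <- c("plateau_one", "ramp_up", "ramp_down", "plateau_two")
  if (!all(need %in% labs))
    stop("command has no plateau labels (ramp protocol?)")
  seg <- cmd$segments
  win <- function(lab) c(seg$start[labs == lab], seg$end[labs == lab])
  structure(
    list(plateau_one = win("plateau_one"),
         ramp = c(seg$start[labs == "ramp_up"], seg$end[labs == "ramp_down"]),
         plateau_two = win("plateau_two")),
    class = "plateau_windows"
  )
}

#' Flag a trial whose torque deviates from the command
#'
#' Marks a trial as deviating when |torque - command| exceeds `tol` %MVT for
#' more than half of the samples in any labelled segment. Flagging is a
#' screen only; no data are dropped.
#'
#' @param trace a [torque_trace()].
#' @param cmd the command profile.
#' @param tol deviation tolerance in %MVT (default 5).
#' @return logical: `TRUE` if the trial should be flagged.
#' @export
flag_deviating_trial <- function(trace, cmd, tol = 5) {
  target <- command_drive_at(cmd, trace$t)
  dev <- abs(trace$torque_pct - target) > tol
  for (k in seq_len(nrow(cmd$segments))) {
    s <- cmd$segments[k, ]
    sel <- trace$t >= s$start & trace$t <= s$end
    if (any(sel) && mean(dev[sel]) > 0.5) return(TRUE)
  }
  FALSE
}
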