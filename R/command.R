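#' Generate a command (target-torque) trajectory
#'
#' Builds the piecewise-linear drive profiles used throughout the package:
#' the superimposition "sombrero" (a triangular ramp atop a sustained
#' stabilization hold), the matched constant hold, and the plain triangular
#' ramp classically used for paired motor-unit analysis.
#'
#' All drives are expressed in percent of maximum voluntary torque (%MVT) and
#' sampled on a uniform grid. The analytic segment breakpoints are stored with
#' the profile so that downstream windows (plateaus, ramp) are never inferred
#' from the sampled signal.
#'
#' @param protocol one of `"sombrero"`, `"hold"`, `"ramp"`.
#' @param mvt_plateau plateau level in %MVT (stabilization hold); sombrero
#'   default 10.
#' @param mvt_peak ramp peak in %MVT; default 30.
#' @param ramp_rate ramp rise/decay speed in %MVT per second; default 3.
#' @param plateau_dur duration of each stabilization plateau in seconds;
#'   default 10.
#' @param fs sampling rate in Hz; default 2048.
#' @return an object of class `command_profile`: list with `t` (s), `drive`
#'   (%MVT), `segments` (data.frame with `label`, `start`, `end`, `v_start`,
#'   `v_end`), `protocol`, `fs`.
#' @details
#' * `sombrero`: plateau at `mvt_plateau` for `plateau_dur`, linear rise to
#'   `mvt_peak` at `ramp_rate`, linear fall back, second plateau of
#'   `plateau_dur`.
#' * `hold`: constant `mvt_plateau` over the full duration of the matching
#'   sombrero; segment windows (`plateau_one`, `ramp_up`, `ramp_down`,
#'   `plateau_two`) are copied from that sombrero so plateau regions are
#'   time-matched between the two contraction types.
#' * `ramp`: 0 to `mvt_peak` and back, i.e. a triangle of total duration
#'   `2 * mvt_peak / ramp_rate`.
#' @examples
#' cmd <- generate_command("sombrero", 10, 30, 3, 10)
#' cmd$segments
#' @export
generate_command <- function(protocol = c("sombrero", "hold", "ramp"),
                             mvt_plateau = 10, mvt_peak = 30,
                             ramp_rate = 3, plateau_dur = 10, fs = 2048) {
  protocol <- match.arg(protocol)
  if (!is.finite(ramp_rate) || ramp_rate <= 0)
    stop("`ramp_rate` must be a positive %MVT/s value")
  if (protocol != "ramp" && (!is.finite(plateau_dur) || plateau_dur <= 0))
    stop("`plateau_dur` must be a positive duration in seconds")
  if (mvt_plateau < 0 || mvt_peak < mvt_plateau)
    stop("require `mvt_peak` >= `mvt_plateau` >= 0")

  ramp_half <- (mvt_peak - mvt_plateau) / ramp_rate
  if (protocol == "ramp") {
    ramp_half <- mvt_peak / ramp_rate
    segments <- data.frame(
      label = c("ramp_up", "ramp_down"),
      start = c(0, ramp_half),
      end = c(ramp_half, 2 * ramp_half),
      v_start = c(0, mvt_peak),
      v_end = c(mvt_peak, 0),
      stringsAsFactors = FALSE
    )
  } else {
    t1 <- plateau_dur
    t2 <- t1 + ramp_half
    t3 <- t2 + ramp_half
    t4 <- t3 + plateau_dur
    segments <- data.frame(
      label = c("plateau_one", "ramp_up", "ramp_down", "plateau_two"),
      start = c(0, t1, t2, t3),
      end = c(t1, t2, t3, t4),
      v_start = c(mvt_plateau, mvt_plateau, mvt_peak, mvt_plateau),
      v_end = c(mvt_plateau, mvt_peak, mvt_plateau, mvt_plateau),
      stringsAsFactors = FALSE
    )
    if (protocol == "hold") {
      # constant drive; windows kept from the matching sombrero
      segments$v_start <- mvt_plateau
      segments$v_end <- mvt_plateau
    }
  }

  total <- segments$end[nrow(segments)]
  t <- seq(0, total, by = 1 / fs)
  if (t[length(t)] < total) t <- c(t, total)
  drive <- eval_segments(segments, t)
  structure(
    list(t = t, drive = drive, segments = segments, protocol = protocol,
         fs = fs,
         params = list(mvt_plateau = mvt_plateau, mvt_peak = mvt_peak,
                       ramp_rate = ramp_rate, plateau_dur = plateau_dur)),
    class = "command_profile"
  )
}

# Evaluate the piecewise-linear segment table at arbitrary times (exact).
eval_segments <- function(segments, t) {
  drive <- numeric(length(t))
  for (k in seq_len(nrow(segments))) {
    s <- segments[k, ]
    sel <- if (k == nrow(segments)) t >= s$start & t <= s$end
           else t >= s$start & t < s$end
    if (!any(sel)) next
    if (s$end > s$start) {
      frac <- (t[sel] - s$start) / (s$end - s$start)
      drive[sel] <- s$v_start + frac * (s$v_end - s$v_start)
    } else {
      drive[sel] <- s$v_start
    }
  }
  drive
}

#' Evaluate a command profile's drive at arbitrary times
#'
#' Uses the stored analytic breakpoints, so values are exact for the
#' piecewise-linear trajectory (no grid interpolation error).
#'
#' @param cmd a `command_profile`.
#' @param times numeric vector of times in seconds within the command span.
#' @return drive values in %MVT.
#' @export
command_drive_at <- function(cmd, times) {
  stopifnot(inherits(cmd, "command_profile"))
  eval_segments(cmd$segments, times)
}

# First time >= `after` at which the drive reaches `level` in the stated
# direction ("up": drive rises to >= level; "down": drive falls below level).
# Solved analytically on the segment table; NA if no crossing. A point where
# the drive merely touches the level while moving the other way (e.g. equals
# it on the ascending limb for a "down" search) is not a crossing.
command_crossing <- function(cmd, level, after = -Inf,
                             direction = c("up", "down")) {
  direction <- match.arg(direction)
  tol <- 1e-9
  seg <- cmd$segments
  for (k in seq_len(nrow(seg))) {
    s <- seg[k, ]
    if (s$end <= after) next
    lo <- max(s$start, after)
    v_lo <- if (s$end > s$start) {
      s$v_start + (lo - s$start) / (s$end - s$start) * (s$v_end - s$v_start)
    } else s$v_start
    if (direction == "up") {
      if (v_lo >= level - tol) return(lo)
      if (s$v_end >= level - tol && s$v_end > v_lo) {
        return(lo + (level - v_lo) / (s$v_end - v_lo) * (s$end - lo))
      }
    } else {
      if (v_lo < level - tol) return(lo)
      decreasing <- s$v_end < v_lo - tol
      if (decreasing && s$v_end < level - tol) {
        if (abs(v_lo - level) <= tol) return(lo)
        return(lo + (v_lo - level) / (v_lo - s$v_end) * (s$end - lo))
      }
    }
  }
  NA_real_
}

# Time and value of the command's global peak (earliest occurrence).
command_peak <- function(cmd) {
  seg <- cmd$segments
  vals <- c(seg$v_start, seg$v_end)
  tms <- c(seg$start, seg$end)
  i <- which.max(vals)
  # ties: earliest time with the max value
  mx <- vals[i]
  t_at <- min(tms[vals >= mx - 1e-12])
  list(t = t_at, value = mx)
}

#' @export
print.command_profile <- function(x, ...) {
  cat(sprintf("<command_profile> %s, %.1f s at %g Hz\n",
              x$protocol, max(x$t), x$fs))
  print(x$segments, row.names = FALSE)
  invisible(x)
}
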