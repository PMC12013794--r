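#' End of maintained discharge for a spike train
#'
#' Discharge is "maintained" while successive inter-spike intervals stay
#' below 1 s; scanning the ISIs in order, discharge ends at the first spike
#' followed by a gap of at least `max_isi` seconds (a gap of exactly 1 s
#' breaks maintained discharge). With no such gap the end is the last spike.
#'
#' @param train a [spike_train()].
#' @param max_isi gap that terminates maintained discharge, s (default 1).
#' @return time of the last maintained discharge (s).
#' @export
discharge_end <- function(train, max_isi = 1) {
  stopifnot(inherits(train, "spike_train"))
  times <- train$times
  if (!length(times)) stop("empty spike train")
  if (length(times) == 1) return(times)
  gaps <- diff(times)
  brk <- which(gaps >= max_isi)
  if (length(brk)) times[brk[1]] else times[length(times)]
}

#' Classify units into brim / button / cap categories
#'
#' For superimposition (sombrero) trials: brim units are recruited during the
#' first stabilization plateau (before the ramp window), button units are
#' recruited in the centre ramp and cease maintained discharge before the
#' second plateau, and cap units are recruited in the centre ramp but sustain
#' discharge into the second plateau. Units recruited during the second
#' plateau are labelled "other".
#'
#' @param trains list of [spike_train()] objects.
#' @param windows a [segment_plateaus()] result.
#' @return data.frame with `unit_id`, `category`, `t_rec`, `t_discharge_end`.
#' @export
classify_units <- function(trains, windows) {
  stopifnot(inherits(windows, "plateau_windows"))
  rows <- lapply(trains, function(tr) {
    if (!length(tr$times)) {
      return(data.frame(unit_id = tr$unit_id, category = NA_character_,
                        t_rec = NA_real_, t_discharge_end = NA_real_,
                        stringsAsFactors = FALSE))
    }
    t_rec <- tr$times[1]
    d_end <- discharge_end(tr)
    cat <- if (t_rec < windows$ramp[1]) "brim"
      else if (t_rec >= windows$plateau_two[1]) "other"
      else if (d_end > windows$plateau_two[1]) "cap"
      else "button"
    data.frame(unit_id = tr$unit_id, category = cat, t_rec = t_rec,
               t_discharge_end = d_end, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Sustained discharge past theoretical derecruitment
#'
#' A unit recruited at torque `tq_rec` on the ascending limb "should" be
#' derecruited when the torque falls back to `tq_rec` on the descending limb
#' (identical recruitment and derecruitment torque). Sustained discharge is
#' the signed time its maintained discharge continues past that theoretical
#' derecruitment instant.
#'
#' The crossing is found on the noiseless command when one is supplied
#' (simulated data; analytic, recruitment level taken from the drive at
#' recruitment), otherwise on the 50 Hz-filtered torque with linear
#' interpolation between samples; the first crossing after the torque peak is
#' used. If the measured torque never falls back to the recruitment level the
#' result is flagged `no_crossing` and the command-domain crossing is used
#' when available.
#'
#' @param train a [spike_train()].
#' @param trace a [torque_trace()] (used when `cmd` is `NULL`).
#' @param windows a [segment_plateaus()] result (context only; may be `NULL`).
#' @param cmd optional [generate_command()] profile for the analytic crossing.
#' @return object of class `sustained_discharge`: list with `unit_id`,
#'   `t_theoretical_derec`, `t_discharge_end`, `sustained_dur` (signed s),
#'   `no_crossing` flag.
#' @export
sustained_duration <- function(train, trace = NULL, windows = NULL,
                               cmd = NULL) {
  stopifnot(inherits(train, "spike_train"))
  if (!length(train$times)) stop("empty spike train")
  t_rec <- train$times[1]
  d_end <- discharge_end(train)
  no_crossing <- FALSE
  t_theo <- NA_real_

  if (!is.null(cmd)) {
    level <- command_drive_at(cmd, t_rec)
    pk <- command_peak(cmd)
    t_theo <- command_crossing(cmd, level, after = pk$t, direction = "down")
    if (is.na(t_theo)) no_crossing <- TRUE
  } else {
    stopifnot(inherits(trace, "torque_trace"))
    tq_rec <- trace$torque_pct[which.min(abs(trace$t - t_rec))]
    i_peak <- which.max(trace$torque_filt)
    tq <- trace$torque_pct
    below <- which(tq[-1] <= tq_rec & seq_along(tq)[-1] > i_peak)
    cross <- NA_real_
    for (j in below) {
      i <- j + 1 # first sample at/below the level after the peak
      if (tq[i - 1] > tq_rec) {
        cross <- trace$t[i - 1] + (tq[i - 1] - tq_rec) /
          (tq[i - 1] - tq[i]) * (trace$t[i] - trace$t[i - 1])
      } else cross <- trace$t[i]
      break
    }
    if (is.na(cross)) no_crossing <- TRUE else t_theo <- cross
  }

  structure(
    list(unit_id = train$unit_id, t_theoretical_derec = t_theo,
         t_discharge_end = d_end,
         sustained_dur = if (is.na(t_theo)) NA_real_ else d_end - t_theo,
         no_crossing = no_crossing),
    class = "sustained_discharge"
  )
}

#' Proportion of ramp-recruited units with long sustained discharge
#'
#' Number of cap units whose sustained discharge exceeds `min_sustained`
#' seconds, divided by the number of units recruited in the centre ramp. The
#' default denominator is the ramp-recruited set (cap + button); the
#' alternative `"cap_brim"` denominator (cap + brim) is also provided.
#'
#' @param categories [classify_units()] output.
#' @param sustained list of [sustained_duration()] results for the cap units
#'   (other categories are ignored).
#' @param min_sustained threshold in seconds (default 2).
#' @param denominator `"ramp"` (cap + button, default) or `"cap_brim"`.
#' @return proportion in \[0, 1\]; `NA` (with a warning) when the
#'   denominator is empty.
#' @export
proportion_sustained <- function(categories, sustained, min_sustained = 2,
                                 denominator = c("ramp", "cap_brim")) {
  denominator <- match.arg(denominator)
  caps <- categories$unit_id[categories$category %in% "cap"]
  sus <- vapply(sustained, function(s) s$sustained_dur, numeric(1))
  ids <- vapply(sustained, function(s) as.character(s$unit_id), character(1))
  n_qual <- sum(ids %in% caps & !is.na(sus) & sus > min_sustained)
  denom_set <- if (denominator == "ramp") c("cap", "button") else
    c("cap", "brim")
  n_denom <- sum(categories$category %in% denom_set)
  if (n_denom == 0) {
    warning("no units in the denominator set; proportion undefined")
    return(NA_real_)
  }
  n_qual / n_denom
}

#' Per-unit change in mean discharge rate between plateaus
#'
#' For units active in both stabilization plateaus (typically brim units):
#' mean smoothed rate over plateau two minus mean over plateau one, each
#' restricted to the unit's active span. Units without support in either
#' plateau are excluded with a reason.
#'
#' @param units list of per-unit lists with elements `sm` ([svr_smooth()])
#'   and `lm` ([landmarks()]), as produced by [analyze_trial()].
#' @param windows a [segment_plateaus()] result.
#' @param trim seconds trimmed from each plateau end (default 0).
#' @return data.frame with `unit_id`, `rate_p1`, `rate_p2`, `delta_rate`
#'   (pps), `excluded_reason`.
#' @export
plateau_rate_delta <- function(units, windows, trim = 0) {
  stopifnot(inherits(windows, "plateau_windows"))
  rows <- lapply(units, function(u) {
    sp <- sm_span(u$sm)
    mean_in <- function(win) {
      lo <- max(win[1] + trim, sp[1]); hi <- min(win[2] - trim, sp[2])
      if (hi <= lo) return(NA_real_)
      mean(rate_at(u$sm, seq(lo, hi, by = 1 / 2048)))
    }
    r1 <- mean_in(windows$plateau_one)
    r2 <- mean_in(windows$plateau_two)
    reason <- if (is.na(r1)) "inactive_plateau_one"
      else if (is.na(r2)) "inactive_plateau_two" else NA_character_
    data.frame(unit_id = u$lm$unit_id, rate_p1 = r1, rate_p2 = r2,
               delta_rate = r2 - r1, excluded_reason = reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
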