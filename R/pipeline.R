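#' Analyze one trial: smooth units, landmarks, categories and delta-F
#'
#' Runs the per-unit pipeline on a trial's spike trains: instantaneous rates,
#' SVR smoothing, recruitment/derecruitment landmarks, and (when the command
#' has plateau labels) brim/button/cap classification with sustained
#' discharge. Delta-F is computed for every unit using all earlier-recruited
#' units as candidate reporters.
#'
#' @param trains list of [spike_train()] objects.
#' @param trace a [torque_trace()].
#' @param cmd optional [generate_command()] profile (enables analytic
#'   plateau windows, classification and sustained-discharge metrics).
#' @param smooth logical; fit SVR curves (default `TRUE`). With `FALSE`,
#'   rate-dependent metrics (delta-F, rate landmarks) are skipped — useful
#'   when only time/torque landmarks are needed.
#' @param delta_f_args list of arguments forwarded to [delta_f()].
#' @param min_spikes units with fewer spikes are dropped (default 4).
#' @return list with `units` (per-unit lists: `train`, `sm`, `lm`,
#'   `category`, `sustained`, `df`) and `metrics` (per-unit data.frame with
#'   columns unit_id, t_rec, tq_rec, t_derec, tq_derec, ascend_dur,
#'   descend_dur, adr, rate_rec, rate_peak, rate_derec, category,
#'   sustained_dur, mean_delta_f, n_pairs).
#' @export
analyze_trial <- function(trains, trace, cmd = NULL, smooth = TRUE,
                          delta_f_args = list(), min_spikes = 4) {
  trains <- Filter(function(tr) length(tr$times) >= min_spikes, trains)
  windows <- NULL
  cats <- NULL
  if (!is.null(cmd) &&
      all(c("plateau_one", "plateau_two") %in% cmd$segments$label)) {
    windows <- segment_plateaus(cmd)
    cats <- classify_units(trains, windows)
  }
  units <- lapply(trains, function(tr) {
    sm <- NULL
    if (smooth) {
      rs <- instantaneous_rates(tr)
      sm <- svr_smooth(rs)
    }
    lm <- landmarks(tr, trace, smoothed = sm)
    u <- list(train = tr, sm = sm, lm = lm)
    if (!is.null(windows)) {
      u$category <- cats$category[match(tr$unit_id, cats$unit_id)]
      if (identical(u$category, "cap") || identical(u$category, "button")) {
        u$sustained <- sustained_duration(tr, trace, windows, cmd = cmd)
      }
    }
    u
  })
  # delta-F per unit against all earlier-recruited units
  rec_times <- vapply(units, function(u) u$lm$t_rec, numeric(1))
  ord <- order(rec_times)
  if (smooth) {
    for (k in seq_along(units)) {
      reporters <- units[ord[rec_times[ord] < rec_times[k]]]
      if (length(reporters)) {
        units[[k]]$df <- do.call(delta_f,
                                 c(list(units[[k]], reporters), delta_f_args))
      }
    }
  }

  metrics <- do.call(rbind, lapply(units, function(u) {
    dm <- descending_metrics(u$lm, trace)
    data.frame(
      unit_id = u$lm$unit_id,
      t_rec = u$lm$t_rec, tq_rec = u$lm$tq_rec,
      t_derec = u$lm$t_derec, tq_derec = u$lm$tq_derec,
      ascend_dur = dm$ascend_dur, descend_dur = dm$descend_dur, adr = dm$adr,
      rate_rec = u$lm$rate_rec, rate_peak = u$lm$rate_peak,
      rate_derec = u$lm$rate_derec,
      category = if (is.null(u$category)) NA_character_ else u$category,
      sustained_dur = if (is.null(u$sustained)) NA_real_
                      else u$sustained$sustained_dur,
      mean_delta_f = if (is.null(u$df)) NA_real_ else u$df$mean_delta_f,
      n_pairs = if (is.null(u$df)) 0L else u$df$n_pairs,
      stringsAsFactors = FALSE)
  }))
  list(units = units, metrics = metrics, windows = windows)
}

#' Write spike trains to JSON (trial -> unit -> times)
#'
#' @param trains list of [spike_train()] objects.
#' @param path output file path.
#' @param trial_id trial identifier used as the top-level key.
#' @export
write_spike_trains_json <- function(trains, path, trial_id = "trial1") {
  units <- lapply(trains, function(tr) tr$times)
  names(units) <- vapply(trains, function(tr) as.character(tr$unit_id),
                         character(1))
  obj <- stats::setNames(list(units), trial_id)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read spike trains from JSON written by [write_spike_trains_json()]
#'
#' @param path input file path.
#' @return named list (per trial) of lists of [spike_train()] objects.
#' @export
read_spike_trains_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(stats::setNames(names(obj), names(obj)), function(trial) {
    units <- obj[[trial]]
    lapply(stats::setNames(names(units), names(units)), function(u) {
      spike_train(as.numeric(units[[u]]), unit_id = u, trial_id = trial)
    })
  })
}

#' Write spike trains as long-format CSV
#'
#' Columns: `trial_id`, `unit_id`, `spike_time_s`.
#' @param trains list of [spike_train()] objects.
#' @param path output file path.
#' @export
write_spike_trains_csv <- function(trains, path) {
  rows <- do.call(rbind, lapply(trains, function(tr) {
    if (!length(tr$times)) return(NULL)
    data.frame(trial_id = tr$trial_id, unit_id = tr$unit_id,
               spike_time_s = tr$times, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write a torque trace as CSV
#'
#' Columns: `t_s`, `torque_nm`, `torque_pct_mvt`.
#' @param trace a [torque_trace()].
#' @param path output file path.
#' @export
write_torque_csv <- function(trace, path) {
  utils::write.csv(data.frame(t_s = trace$t, torque_nm = trace$torque_raw,
                              torque_pct_mvt = trace$torque_pct),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a torque trace from CSV
#'
#' Expects columns `t_s`, `torque_nm`; `mvt` may be supplied or recovered
#' from an optional `torque_pct_mvt` column.
#' @param path input file path.
#' @param mvt maximum voluntary torque in Nm (optional if the file carries
#'   `torque_pct_mvt`).
#' @param fs sampling rate in Hz (inferred from `t_s` when omitted).
#' @return a [torque_trace()].
#' @export
read_torque_csv <- function(path, mvt = NULL, fs = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("t_s", "torque_nm") %in% names(df)))
  if (is.null(fs)) fs <- round(1 / stats::median(diff(df$t_s)))
  if (is.null(mvt)) {
    if (!"torque_pct_mvt" %in% names(df))
      stop("supply `mvt` or a torque_pct_mvt column")
    # %MVT is derived from the filtered signal, so recover the constant from
    # the filtered raw column rather than sample-wise raw/pct ratios
    filt <- filter_torque(df$torque_nm, fs)
    sel <- abs(df$torque_pct_mvt) >
      0.2 * stats::quantile(abs(df$torque_pct_mvt), 0.9)
    mvt <- 100 * stats::median(filt[sel] / df$torque_pct_mvt[sel])
  }
  torque_trace(df$t_s, df$torque_nm, mvt = mvt, fs = fs)
}
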