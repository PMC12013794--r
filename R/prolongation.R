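#' Recruitment/derecruitment landmarks for a motor unit
#'
#' Recruitment and derecruitment are the unit's first and last discharge
#' times; the associated torques are read from the %MVT trace at the nearest
#' sample, and the discharge-rate landmarks from the smoothed rate curve.
#'
#' @param train a [spike_train()].
#' @param trace a [torque_trace()] covering the train's span.
#' @param smoothed optional [svr_smooth()] curve for the unit; when omitted
#'   the rate landmarks (`rate_rec`, `rate_peak`, `rate_derec`) are `NA`.
#' @return object of class `mu_landmarks`: list with `t_rec`, `t_derec`,
#'   `tq_rec`, `tq_derec` (%MVT), `rate_rec`, `rate_peak`, `rate_derec`
#'   (pps), `unit_id`.
#' @export
landmarks <- function(train, trace, smoothed = NULL) {
  stopifnot(inherits(train, "spike_train"), inherits(trace, "torque_trace"))
  if (!length(train$times)) stop("empty spike train has no landmarks")
  t_rec <- train$times[1]
  t_derec <- train$times[length(train$times)]
  if (t_rec < min(trace$t) - 1e-9 || t_derec > max(trace$t) + 1e-9)
    stop("torque trace does not cover the spike train span")
  tq_at <- function(tt) trace$torque_pct[which.min(abs(trace$t - tt))]
  rate_rec <- rate_peak <- rate_derec <- NA_real_
  if (!is.null(smoothed)) {
    rate_rec <- smoothed$rate[1]
    rate_derec <- smoothed$rate[length(smoothed$rate)]
    rate_peak <- max(smoothed$rate)
  }
  structure(
    list(t_rec = t_rec, t_derec = t_derec,
         tq_rec = tq_at(t_rec), tq_derec = tq_at(t_derec),
         rate_rec = rate_rec, rate_peak = rate_peak, rate_derec = rate_derec,
         unit_id = train$unit_id),
    class = "mu_landmarks"
  )
}

#' Squared rate-rate correlation between two smoothed discharge curves
#'
#' Pearson r^2 between the test and reporter smoothed rates, resampled on a
#' common 2048 Hz grid over the test unit's active span (intersected with
#' both supports). Used as the common-drive screen of the paired-unit
#' analysis.
#'
#' @param test,reporter [svr_smooth()] curves.
#' @param span optional length-2 span (s); default: the test curve's support.
#' @param fs resampling rate in Hz.
#' @return r^2 in \[0, 1\], or `NA` if either curve has zero variance over
#'   the common span (e.g. a constant reporter).
#' @export
rate_rate_r2 <- function(test, reporter, span = NULL, fs = 2048) {
  stopifnot(inherits(test, "smoothed_rate"), inherits(reporter, "smoothed_rate"))
  if (is.null(span)) span <- sm_span(test)
  lo <- max(span[1], sm_span(test)[1], sm_span(reporter)[1])
  hi <- min(span[2], sm_span(test)[2], sm_span(reporter)[2])
  if (hi <= lo) return(NA_real_)
  grid <- seq(lo, hi, by = 1 / fs)
  x <- rate_at(test, grid)
  y <- rate_at(reporter, grid)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Paired motor-unit delta-F estimate
#'
#' Delta-F quantifies PIC magnitude as the hysteresis of a higher-threshold
#' (test) unit referenced to the smoothed discharge rate of lower-threshold
#' (reporter) units: for each reporter,
#' `deltaF = reporter_rate(test recruitment) - reporter_rate(test
#' derecruitment)`, so PIC-induced hysteresis yields positive values. The
#' test-unit value is the mean over all surviving reporter pairs.
#'
#' Reporter pairs are excluded when (a) the rate-rate correlation r^2 is not
#' above `r2_min` (common-drive screen), (b) the recruitment time difference
#' is below `min_rec_diff` (reporter PIC not yet fully activated), or (c) the
#' reporter's smoothed-rate range while the test unit is active is below
#' `min_range` pps (saturated reporter). Reporters not recruited before the
#' test unit, or whose smoothed support does not cover both test landmarks,
#' are ineligible and not listed as pairs.
#'
#' @param test list with elements `sm` ([svr_smooth()] curve) and `lm`
#'   ([landmarks()]) for the test unit (as produced by [analyze_trial()]).
#' @param reporters list of such lists for candidate reporter units.
#' @param r2_min exclusion threshold on r^2 (pairs kept only if r^2 >
#'   `r2_min`; default 0.7).
#' @param min_rec_diff minimum recruitment time difference in s (default 1).
#' @param min_range minimum reporter discharge range in pps while the test
#'   unit is active (default 0.5).
#' @return object of class `delta_f_result`: list with `test_id`, `pairs`
#'   (data.frame: reporter_id, delta_f, r2, rec_time_diff, reporter_range,
#'   excluded_reason), `mean_delta_f` (NA when no pair survives), `n_pairs`.
#' @export
delta_f <- function(test, reporters, r2_min = 0.7, min_rec_diff = 1,
                    min_range = 0.5) {
  stopifnot(!is.null(test$sm), !is.null(test$lm))
  t_rec <- test$lm$t_rec
  t_derec <- test$lm$t_derec
  pairs <- list()
  for (rep_u in reporters) {
    if (is.null(rep_u$sm) || is.null(rep_u$lm)) next
    if (!(rep_u$lm$t_rec < t_rec)) next # must be lower threshold / earlier
    sp <- sm_span(rep_u$sm)
    if (sp[1] > t_rec + 1e-9 || sp[2] < t_derec - 1e-9) next # not covering
    rec_diff <- t_rec - rep_u$lm$t_rec
    r2 <- rate_rate_r2(test$sm, rep_u$sm)
    lo <- max(t_rec, sp[1]); hi <- min(t_derec, sp[2])
    grid <- seq(lo, hi, by = 1 / 2048)
    rng <- diff(range(rate_at(rep_u$sm, grid)))
    dfv <- rate_at(rep_u$sm, t_rec) - rate_at(rep_u$sm, t_derec)
    reason <- NA_character_
    if (rec_diff < min_rec_diff) {
      reason <- "rec_time_diff"
    } else if (is.na(r2)) {
      reason <- "r2_undefined"
    } else if (r2 <= r2_min) {
      reason <- "low_r2"
    } else if (rng < min_range) {
      reason <- "reporter_range"
    }
    pairs[[length(pairs) + 1]] <- data.frame(
      reporter_id = rep_u$lm$unit_id, delta_f = dfv, r2 = r2,
      rec_time_diff = rec_diff, reporter_range = rng,
      excluded_reason = reason, stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(reporter_id = character(0), delta_f = numeric(0),
               r2 = numeric(0), rec_time_diff = numeric(0),
               reporter_range = numeric(0), excluded_reason = character(0),
               stringsAsFactors = FALSE)
  surviving <- pairs[is.na(pairs$excluded_reason), , drop = FALSE]
  structure(
    list(test_id = test$lm$unit_id, pairs = pairs,
         mean_delta_f = if (nrow(surviving)) mean(surviving$delta_f)
                        else NA_real_,
         n_pairs = nrow(surviving)),
    class = "delta_f_result"
  )
}

#' @export
print.delta_f_result <- function(x, ...) {
  cat(sprintf("<delta_f_result> test %s: mean deltaF = %s pps over %d pairs (%d candidates)\n",
              x$test_id,
              if (is.na(x$mean_delta_f)) "NA" else sprintf("%.2f", x$mean_delta_f),
              x$n_pairs, nrow(x$pairs)))
  invisible(x)
}

#' Descending-phase discharge metrics for a ramp contraction
#'
#' Durations of discharge on the ascending and descending limbs relative to
#' the trial's peak torque, and their normalized difference (ADR). Peak
#' torque is taken from the 50 Hz-filtered trace (earliest sample on ties);
#' negative durations (derecruitment before the torque peak) are reported
#' signed, not clipped.
#'
#' @param lm a [landmarks()] result.
#' @param trace a [torque_trace()].
#' @return object of class `ramp_metrics`: list with `ascend_dur`,
#'   `descend_dur` (s, signed), `adr` = (ascend - descend)/(total discharge
#'   duration), `tq_derec` (%MVT), `t_peak_torque`, and the landmarks.
#' @export
descending_metrics <- function(lm, trace) {
  stopifnot(inherits(lm, "mu_landmarks"), inherits(trace, "torque_trace"))
  i_peak <- which.max(trace$torque_filt) # which.max takes first on ties
  t_peak <- trace$t[i_peak]
  ascend <- t_peak - lm$t_rec
  descend <- lm$t_derec - t_peak
  total <- lm$t_derec - lm$t_rec
  structure(
    list(ascend_dur = ascend, descend_dur = descend,
         adr = if (total > 0) (ascend - descend) / total else NA_real_,
         tq_derec = lm$tq_derec, t_peak_torque = t_peak, landmarks = lm),
    class = "ramp_metrics"
  )
}
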