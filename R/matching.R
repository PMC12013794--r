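#' Construct a MUAP template
#'
#' A motor-unit action potential template over a multichannel electrode grid:
#' one waveform per channel over a common time window.
#'
#' @param waveform numeric matrix, channels x samples.
#' @param grid integer length-2, grid rows x cols (default 13 x 5).
#' @param channel_map data.frame with `channel`, `row`, `col` mapping matrix
#'   rows to grid coordinates; default row-major full grid.
#' @param center length-2 grid coordinates (row, col) of the spatial peak;
#'   computed from channel RMS when omitted.
#' @param fs sampling rate in Hz.
#' @param n_spikes number of spikes averaged (for STA templates).
#' @param absent optional integer vector of absent channel indices.
#' @return object of class `muap_template`.
#' @export
muap_template <- function(waveform, grid = c(13, 5), channel_map = NULL,
                          center = NULL, fs = 2048, n_spikes = NA_integer_,
                          absent = integer(0)) {
  stopifnot(is.matrix(waveform), all(is.finite(waveform[setdiff(
    seq_len(nrow(waveform)), absent), ])))
  if (is.null(channel_map)) channel_map <- default_channel_map(grid)
  if (is.null(center)) {
    rms <- sqrt(rowMeans(waveform^2))
    rms[absent] <- -Inf
    i <- which.max(rms)
    center <- c(channel_map$row[i], channel_map$col[i])
  }
  structure(
    list(waveform = waveform, grid = grid, channel_map = channel_map,
         center = center, fs = fs, n_spikes = n_spikes, absent = absent),
    class = "muap_template"
  )
}

default_channel_map <- function(grid = c(13, 5)) {
  data.frame(channel = seq_len(prod(grid)),
             row = rep(seq_len(grid[1]), times = grid[2]),
             col = rep(seq_len(grid[2]), each = grid[1]))
}

#' @export
print.muap_template <- function(x, ...) {
  cat(sprintf("<muap_template> %dx%d grid, %d channels x %d samples, center (%d,%d)\n",
              x$grid[1], x$grid[2], nrow(x$waveform), ncol(x$waveform),
              x$center[1], x$center[2]))
  invisible(x)
}

#' Synthesize MUAP templates and multichannel surface EMG
#'
#' Each unit receives a biphasic wavelet time course whose per-channel
#' amplitude follows a spatial Gaussian centred at a (random or supplied)
#' electrode-grid coordinate. The EMG is the sum of every unit's template
#' placed at its spike times, plus white noise at the stated channel-average
#' SNR. The generating templates are returned as ground truth for matching
#' tests.
#'
#' @param trains list of [spike_train()] objects.
#' @param duration record length in seconds.
#' @param grid grid rows x cols (default `c(13, 5)`, the 64+1-channel array
#'   layout).
#' @param snr_db signal-to-noise ratio in dB; `Inf` for noiseless.
#' @param seed integer seed.
#' @param centers optional matrix (units x 2) of spatial centres (row, col);
#'   supply to reuse unit identities across trials.
#' @param fs sampling rate in Hz.
#' @param window_half half-width of the template window in s (default 0.025).
#' @param spatial_sd spatial Gaussian SD in electrode pitches (default 1.2).
#' @return list with `templates` (list of [muap_template()]), `emg` (samples
#'   x channels matrix), `centers`, `channel_map`, `fs`.
#' @export
synthesize_muaps_and_emg <- function(trains, duration, grid = c(13, 5),
                                     snr_db = 15, seed = 1L, centers = NULL,
                                     fs = 2048, window_half = 0.025,
                                     spatial_sd = 1.2) {
  stopifnot(is.finite(snr_db) || is.infinite(snr_db))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  n_units <- length(trains)
  n_ch <- prod(grid)
  cmap <- default_channel_map(grid)
  if (is.null(centers)) {
    centers <- cbind(sample(seq(2, grid[1] - 1), n_units, replace = TRUE),
                     sample(seq_len(grid[2]), n_units, replace = TRUE))
  }
  half <- round(window_half * fs)
  wt <- (-half:half) / fs
  n_s <- round(duration * fs) + 1
  emg <- matrix(0, nrow = n_s, ncol = n_ch)
  templates <- vector("list", n_units)

  for (i in seq_len(n_units)) {
    # biphasic wavelet: Gaussian-windowed sine, per-unit frequency/width
    f0 <- 90 + 10 * ((i - 1) %% 5)
    sig_t <- 0.003 + 0.0002 * ((i - 1) %% 4)
    wav <- sin(2 * pi * f0 * wt) * exp(-wt^2 / (2 * sig_t^2))
    d2 <- (cmap$row - centers[i, 1])^2 + (cmap$col - centers[i, 2])^2
    w_sp <- exp(-d2 / (2 * spatial_sd^2))
    amp <- 0.5 + 1.5 * i / n_units # larger units later in the pool
    tpl <- amp * outer(w_sp, wav) # channels x samples
    templates[[i]] <- muap_template(tpl, grid = grid, channel_map = cmap,
                                    center = centers[i, ], fs = fs)
    times <- trains[[i]]$times
    if (!length(times)) next
    temporal <- numeric(n_s)
    idx <- round(times * fs) + 1
    idx <- idx[idx >= 1 & idx <= n_s]
    for (j in idx) temporal[j] <- temporal[j] + 1
    sig <- fft_convolve(temporal, wav, half + n_s)[(half + 1):(half + n_s)]
    emg <- emg + amp * outer(sig, w_sp)
  }

  if (is.finite(snr_db)) {
    p_sig <- mean(apply(emg, 2, stats::var))
    p_noise <- p_sig / 10^(snr_db / 10)
    emg <- emg + matrix(stats::rnorm(length(emg), sd = sqrt(p_noise)),
                        nrow = n_s)
  }
  list(templates = templates, emg = emg, centers = centers,
       channel_map = cmap, fs = fs)
}

#' Spike-triggered average MUAP estimation
#'
#' Per channel, the mean of EMG windows centred on each spike. Spikes whose
#' window extends beyond the record are dropped; the number of averaged
#' spikes is recorded and templates with fewer than `min_spikes` usable
#' spikes are flagged low-confidence.
#'
#' @param emg samples x channels EMG matrix.
#' @param train a [spike_train()].
#' @param fs sampling rate in Hz.
#' @param window_half half-width of the averaging window in s (default
#'   0.025, i.e. +/-25 ms).
#' @param grid grid layout.
#' @param min_spikes confidence floor (default 10).
#' @return a [muap_template()] with `n_spikes` set; attribute
#'   `low_confidence` is `TRUE` when fewer than `min_spikes` windows were
#'   averaged.
#' @export
spike_triggered_average <- function(emg, train, fs = 2048,
                                    window_half = 0.025, grid = c(13, 5),
                                    min_spikes = 10) {
  stopifnot(is.matrix(emg), inherits(train, "spike_train"))
  half <- round(window_half * fs)
  n_s <- nrow(emg)
  idx <- round(train$times * fs) + 1
  idx <- idx[idx - half >= 1 & idx + half <= n_s]
  n_used <- length(idx)
  acc <- matrix(0, nrow = ncol(emg), ncol = 2 * half + 1)
  for (j in idx) acc <- acc + t(emg[(j - half):(j + half), , drop = FALSE])
  if (n_used > 0) acc <- acc / n_used
  tpl <- muap_template(acc, grid = grid, fs = fs, n_spikes = n_used)
  attr(tpl, "low_confidence") <- n_used < min_spikes
  tpl
}

#' Normalized 2-D cross-correlation between MUAP templates
#'
#' Both templates are restricted to their common (non-absent) channels,
#' mean-subtracted and unit-normalized over the full channel x time
#' representation; the correlation is the maximum over time lags (default
#' +/-5 ms) of the normalized inner product. Identical templates give
#' exactly 1.
#'
#' @param a,b [muap_template()] objects on the same grid geometry.
#' @param max_lag lag search half-range in s (default 0.005).
#' @param min_common minimum fraction of grid channels that must be present
#'   in both templates (default 0.75).
#' @return correlation in \[-1, 1\].
#' @export
xcorr2_normalized <- function(a, b, max_lag = 0.005, min_common = 0.75) {
  stopifnot(inherits(a, "muap_template"), inherits(b, "muap_template"))
  if (!identical(a$grid, b$grid) || ncol(a$waveform) != ncol(b$waveform))
    stop("templates have mismatched grid geometry")
  common <- setdiff(seq_len(nrow(a$waveform)), union(a$absent, b$absent))
  if (length(common) < min_common * prod(a$grid))
    stop("fewer than the required fraction of common channels")
  wa <- a$waveform[common, , drop = FALSE]
  wb <- b$waveform[common, , drop = FALSE]
  n_t <- ncol(wa)
  lag_n <- round(max_lag * a$fs)
  lags <- -lag_n:lag_n
  best <- -Inf
  for (L in lags) {
    ia <- max(1, 1 + L):min(n_t, n_t + L)
    ib <- ia - L
    xa <- wa[, ia, drop = FALSE]; xb <- wb[, ib, drop = FALSE]
    xa <- xa - mean(xa); xb <- xb - mean(xb)
    den <- sqrt(sum(xa^2) * sum(xb^2))
    if (den == 0) next
    best <- max(best, sum(xa * xb) / den)
  }
  if (!is.finite(best)) NA_real_ else best
}

#' Assign cross-trial motor-unit matches
#'
#' Greedy one-to-one assignment: pair correlations are sorted in descending
#' order (unit-id tie-break, making the result independent of input
#' ordering), and a pair is accepted when its correlation exceeds the
#' threshold and neither endpoint is already matched within that trial pair.
#' Accepted pairs are chained across trials and each chain receives a single
#' unique MU identifier; unmatched units keep solo identifiers.
#'
#' @param pairs data.frame with columns `trial_a`, `unit_a`, `trial_b`,
#'   `unit_b`, `corr` (all cross-trial correlations).
#' @param threshold minimum correlation for a match (default 0.8, strict).
#' @return object of class `match_result`: list with `matched` (accepted
#'   pairs with `mu_uid`), `units` (data.frame trial, unit, mu_uid for every
#'   unit seen), `threshold`.
#' @export
assign_matches <- function(pairs, threshold = 0.8) {
  need <- c("trial_a", "unit_a", "trial_b", "unit_b", "corr")
  stopifnot(all(need %in% names(pairs)))
  key <- function(tr, u) paste(tr, u, sep = "::")
  all_units <- unique(rbind(
    data.frame(trial = pairs$trial_a, unit = pairs$unit_a,
               stringsAsFactors = FALSE),
    data.frame(trial = pairs$trial_b, unit = pairs$unit_b,
               stringsAsFactors = FALSE)))
  ord <- order(-pairs$corr, pairs$trial_a, pairs$unit_a, pairs$trial_b,
               pairs$unit_b)
  pairs <- pairs[ord, , drop = FALSE]

  parent <- stats::setNames(key(all_units$trial, all_units$unit),
                            key(all_units$trial, all_units$unit))
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  used <- character(0) # "trialA|trialB|side|unit" occupancy per trial pair
  accepted <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    p <- pairs[k, ]
    if (!(p$corr > threshold)) next
    tp <- paste(sort(c(p$trial_a, p$trial_b)), collapse = "|")
    ka <- paste(tp, "a", key(p$trial_a, p$unit_a))
    kb <- paste(tp, "b", key(p$trial_b, p$unit_b))
    if (ka %in% used || kb %in% used) next
    used <- c(used, ka, kb)
    ra <- find(key(p$trial_a, p$unit_a))
    rb <- find(key(p$trial_b, p$unit_b))
    if (ra != rb) parent[[rb]] <- ra
    accepted[k] <- TRUE
  }
  roots <- vapply(key(all_units$trial, all_units$unit), find, character(1))
  uid <- match(roots, unique(roots))
  units <- data.frame(trial = all_units$trial, unit = all_units$unit,
                      mu_uid = paste0("MU", uid), stringsAsFactors = FALSE)
  matched <- pairs[accepted, , drop = FALSE]
  if (nrow(matched)) {
    matched$mu_uid <- units$mu_uid[match(key(matched$trial_a, matched$unit_a),
                                         key(units$trial, units$unit))]
  } else matched$mu_uid <- character(0)
  structure(list(matched = matched, units = units, threshold = threshold),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d accepted pairs (> %.2f), %d units, %d unique MUs\n",
              nrow(x$matched), x$threshold, nrow(x$units),
              length(unique(x$units$mu_uid))))
  invisible(x)
}

#' All cross-trial template correlations
#'
#' Convenience wrapper computing [xcorr2_normalized()] for every unit pair
#' across two trials.
#'
#' @param templates_a,templates_b lists of [muap_template()] objects.
#' @param trial_a,trial_b trial identifiers.
#' @param ... passed to [xcorr2_normalized()].
#' @return data.frame suitable for [assign_matches()].
#' @export
cross_trial_correlations <- function(templates_a, templates_b,
                                     trial_a = "A", trial_b = "B", ...) {
  rows <- list()
  for (i in seq_along(templates_a)) {
    for (j in seq_along(templates_b)) {
      rows[[length(rows) + 1]] <- data.frame(
        trial_a = trial_a, unit_a = paste0("u", i),
        trial_b = trial_b, unit_b = paste0("u", j),
        corr = xcorr2_normalized(templates_a[[i]], templates_b[[j]], ...),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
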