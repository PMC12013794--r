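#' Instantaneous discharge rates from a spike train
#'
#' The reciprocal of each inter-spike interval, attributed to the later spike
#' of the pair.
#'
#' @param train a [spike_train()].
#' @return object of class `rate_samples`: list with `t` (s), `rate` (pps),
#'   `unit_id`, and `insufficient` flag (`TRUE` when fewer than two spikes).
#' @examples
#' instantaneous_rates(spike_train(c(0, 0.1, 0.2)))$rate # 10 10
#' @export
instantaneous_rates <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  times <- train$times
  if (length(times) < 2) {
    return(structure(list(t = numeric(0), rate = numeric(0),
                          unit_id = train$unit_id, insufficient = TRUE),
                     class = "rate_samples"))
  }
  isi <- diff(times)
  structure(list(t = times[-1], rate = 1 / isi, unit_id = train$unit_id,
                 insufficient = FALSE),
            class = "rate_samples")
}

#' Smooth instantaneous discharge rates with support vector regression
#'
#' Fits an epsilon-insensitive (L1 soft-margin) support vector regression of
#' rate on time with a radial-basis kernel, and evaluates the fitted curve on
#' a uniform grid spanning the unit's active interval. This produces the
#' smooth, continuous discharge-rate estimate used by all landmark- and
#' delta-F computations. With fewer than four rate samples the smoother falls
#' back to linear interpolation and flags the result.
#'
#' @param samples a [instantaneous_rates()] result.
#' @param span length-2 numeric (s); evaluation span, by default the unit's
#'   \[first spike, last spike\] interval (first sample time minus its ISI to
#'   last sample time).
#' @param fs evaluation grid rate in Hz (default 2048).
#' @param lengthscale RBF kernel length-scale in seconds (default 1, the
#'   timescale of the contraction paradigms).
#' @param cost regularization weight C (default 10).
#' @param epsilon epsilon-insensitive tube half-width in pps (default 0.1).
#' @return object of class `smoothed_rate`: list with `t`, `rate`,
#'   `unit_id`, `method` ("svr" or "linear"), `model_params`.
#' @export
svr_smooth <- function(samples, span = NULL, fs = 2048,
                       lengthscale = 1, cost = 10, epsilon = 0.1) {
  stopifnot(inherits(samples, "rate_samples"))
  if (isTRUE(samples$insufficient) || length(samples$t) < 1)
    stop("no rate samples to smooth (fewer than two spikes)")
  if (anyDuplicated(samples$t))
    stop("duplicate sample times are degenerate for rate smoothing")
  if (is.null(span)) {
    first_spike <- samples$t[1] - 1 / samples$rate[1]
    span <- c(first_spike, samples$t[length(samples$t)])
  }
  t_grid <- seq(span[1], span[2], by = 1 / fs)
  if (t_grid[length(t_grid)] < span[2]) t_grid <- c(t_grid, span[2])

  # regression abscissa: the centre of each ISI, where the reciprocal
  # estimates the instantaneous rate without the half-interval lag that the
  # later-spike reporting convention would otherwise imprint on the curve
  t_fit <- samples$t - 1 / (2 * samples$rate)

  if (length(samples$t) < 4) {
    rate <- stats::approx(t_fit, samples$rate, xout = t_grid,
                          rule = 2)$y
    return(structure(list(t = t_grid, rate = rate, unit_id = samples$unit_id,
                          method = "linear",
                          model_params = list(reason = "fewer than 4 samples")),
                     class = "smoothed_rate"))
  }

  gamma <- 1 / (2 * lengthscale^2)
  fit <- e1071::svm(x = matrix(t_fit, ncol = 1), y = samples$rate,
                    type = "eps-regression", kernel = "radial",
                    gamma = gamma, cost = cost, epsilon = epsilon,
                    scale = FALSE, fitted = FALSE)
  rate <- if (fit$tot.nSV == 0) {
    # every sample inside the epsilon tube: flat minimal-norm solution
    rep(mean(samples$rate), length(t_grid))
  } else {
    as.numeric(stats::predict(fit, matrix(t_grid, ncol = 1)))
  }
  structure(
    list(t = t_grid, rate = rate, unit_id = samples$unit_id, method = "svr",
         model_params = list(kernel = "radial", lengthscale = lengthscale,
                             gamma = gamma, cost = cost, epsilon = epsilon,
                             n_sv = fit$tot.nSV)),
    class = "smoothed_rate"
  )
}

#' @export
print.smoothed_rate <- function(x, ...) {
  cat(sprintf("<smoothed_rate> unit %s, [%.3f, %.3f] s, %d points (%s)\n",
              x$unit_id, min(x$t), max(x$t), length(x$t), x$method))
  invisible(x)
}

#' Evaluate a smoothed rate curve at arbitrary times
#'
#' Linear interpolation on the evaluation grid; `NA` outside the curve's
#' support (no extrapolation beyond the active interval).
#'
#' @param sm a [svr_smooth()] result.
#' @param times numeric vector of times in seconds.
#' @return rates in pps (`NA` outside support).
#' @export
rate_at <- function(sm, times) {
  stopifnot(inherits(sm, "smoothed_rate"))
  stats::approx(sm$t, sm$rate, xout = times, rule = 1)$y
}

# Support span of a smoothed curve.
sm_span <- function(sm) range(sm$t)
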