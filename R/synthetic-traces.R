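#' Calcium trace container
#'
#' A uniformly sampled 1-D fluorescence time series from one embryo's trunk
#' muscle ROI. Default sampling mirrors the confocal time-lapse protocol:
#' one frame every 2.5 minutes for 16 hours.
#'
#' @param times_min Strictly increasing, uniformly spaced times in minutes.
#' @param values Fluorescence values (same length as `times_min`).
#' @param embryo_id,treatment Optional labels carried through the analysis.
#' @return An object of class `calcium_trace`.
#' @export
calcium_trace <- function(times_min, values, embryo_id = "embryo1",
                          treatment = "control") {
  if (length(times_min) < 3) stop("trace needs >= 3 samples", call. = FALSE)
  if (length(times_min) != length(values))
    stop("times and values differ in length", call. = FALSE)
  dts <- diff(times_min)
  if (any(dts <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (diff(range(dts)) > 1e-9)
    stop("sampling must be uniform (constant dt)", call. = FALSE)
  structure(list(times_min = as.numeric(times_min),
                 values = as.numeric(values),
                 dt_min = dts[1],
                 embryo_id = embryo_id, treatment = treatment),
            class = "calcium_trace")
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat(sprintf("<calcium_trace> %s (%s): %d samples, dt = %g min, %.4g-%.4g\n",
              x$embryo_id, x$treatment, length(x$values), x$dt_min,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Simulate a GCaMP calcium trace with known spike truth
#'
#' The trace is `baseline + drift * t + sum of spikes + noise`, where each
#' spike rises instantaneously at its onset time and decays exponentially
#' with time constant `decay_tau_min`. Spike times are either given
#' explicitly or drawn from a homogeneous Poisson process with rate
#' `spike_rate_per_min`; amplitudes are either given explicitly or drawn
#' from a Gamma distribution with mean `amplitude_mean` and coefficient of
#' variation `amplitude_cv`, floored at `amplitude_min` (default 25, i.e.
#' five times the default noise sd: the generator emulates clearly
#' supra-threshold muscle transients, not threshold-straddling events).
#'
#' @param duration_min Trace duration in minutes (default 960 = 16 h).
#' @param dt_min Sampling interval in minutes (default 2.5).
#' @param baseline Baseline fluorescence level.
#' @param drift_slope Linear baseline drift per minute.
#' @param spike_times Explicit spike onset times (minutes), or `NULL` to draw
#'   from a Poisson process. Drawn times are snapped to the sampling grid:
#'   at a 2.5-minute frame interval the sub-frame onset time is not
#'   observable, so the generator places onsets on frame boundaries (two
#'   spikes landing in one frame superimpose).
#' @param spike_rate_per_min Poisson rate, used when `spike_times` is `NULL`.
#' @param spike_amplitudes Explicit amplitudes matching `spike_times`, or
#'   `NULL` to draw from the Gamma model.
#' @param amplitude_mean,amplitude_cv Gamma amplitude model (mean 50, CV 0.3).
#' @param amplitude_min Lower floor applied to drawn amplitudes.
#' @param decay_tau_min Exponential decay time constant (minutes); the
#'   default 5 makes a transient span ~2 frames at 2.5-min sampling.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Integer seed; identical inputs give identical traces.
#' @param embryo_id,treatment Labels for the trace.
#' @return A list with `trace` (a [calcium_trace()]) and `truth`: spike
#'   onset times and instantaneous amplitudes, the grid-sampled peak times
#'   and heights (`sampled_peak_times_min`, `sampled_heights`: the noiseless
#'   above-baseline value at each spike's first sampled frame, the natural
#'   reference for detector evaluation), inter-spike intervals, and the
#'   generator parameters.
#' @export
simulate_calcium_trace <- function(duration_min = 960, dt_min = 2.5,
                                   baseline = 100, drift_slope = 0,
                                   spike_times = NULL,
                                   spike_rate_per_min = 0.02,
                                   spike_amplitudes = NULL,
                                   amplitude_mean = 50, amplitude_cv = 0.3,
                                   amplitude_min = 25, decay_tau_min = 5,
                                   noise_sd = 5,
                                   seed = 1L,
                                   embryo_id = "embryo1",
                                   treatment = "control") {
  if (dt_min <= 0) stop("dt_min must be positive", call. = FALSE)
  if (decay_tau_min <= 0) stop("decay_tau_min must be positive", call. = FALSE)
  if (duration_min < 2 * dt_min)
    stop("duration must be at least two sampling intervals", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  set.seed(seed)
  if (is.null(spike_times)) {
    n_spikes <- stats::rpois(1, spike_rate_per_min * duration_min)
    spike_times <- sort(round(stats::runif(n_spikes, 0, duration_min) /
                                dt_min) * dt_min)
  } else {
    spike_times <- sort(as.numeric(spike_times))
    if (length(spike_times) &&
        (min(spike_times) < 0 || max(spike_times) > duration_min))
      stop("spike times must lie within [0, duration]", call. = FALSE)
  }
  n_spikes <- length(spike_times)
  if (is.null(spike_amplitudes)) {
    if (n_spikes > 0) {
      shape <- 1 / amplitude_cv^2
      spike_amplitudes <- pmax(stats::rgamma(n_spikes, shape = shape,
                                             scale = amplitude_mean / shape),
                               amplitude_min)
    } else spike_amplitudes <- numeric(0)
  } else {
    spike_amplitudes <- as.numeric(spike_amplitudes)
    if (length(spike_amplitudes) != n_spikes)
      stop("spike_amplitudes must match spike_times in length", call. = FALSE)
    if (any(spike_amplitudes <= 0))
      stop("spike amplitudes must be positive", call. = FALSE)
  }
  t <- seq(0, duration_min, by = dt_min)
  spike_sum <- numeric(length(t))
  for (i in seq_len(n_spikes)) {
    after <- t >= spike_times[i]
    spike_sum[after] <- spike_sum[after] +
      spike_amplitudes[i] * exp(-(t[after] - spike_times[i]) / decay_tau_min)
  }
  signal <- baseline + drift_slope * t + spike_sum
  # what each spike looks like on the sampling grid: the noiseless
  # above-baseline value at its first sampled frame (overlapping tails of
  # earlier spikes included) -- the right reference for detector evaluation
  first_idx <- vapply(spike_times, function(ts) which(t >= ts)[1], integer(1))
  values <- signal
  if (noise_sd > 0) values <- values + stats::rnorm(length(t), sd = noise_sd)
  list(
    trace = calcium_trace(t, values, embryo_id = embryo_id,
                          treatment = treatment),
    truth = list(spike_times_min = spike_times,
                 spike_amplitudes = spike_amplitudes,
                 sampled_peak_times_min = t[first_idx],
                 sampled_heights = spike_sum[first_idx],
                 intervals_min = if (n_spikes > 1) diff(spike_times) else numeric(0),
                 decay_tau_min = decay_tau_min, baseline_level = baseline,
                 drift_slope = drift_slope, noise_sd = noise_sd,
                 dt_min = dt_min, duration_min = duration_min, seed = seed)
  )
}
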