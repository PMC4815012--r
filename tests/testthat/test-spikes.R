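test_that("baseline estimation follows constants, ramps and drifting truth", {
  flat <- calcium_trace(seq(0, 500, by = 2.5), rep(42, 201))
  expect_true(all(estimate_baseline(flat) == 42))

  ramp_vals <- 100 + 0.2 * seq(0, 500, by = 2.5)
  ramp <- calcium_trace(seq(0, 500, by = 2.5), ramp_vals)
  bl <- estimate_baseline(ramp, window_min = 50)
  # a percentile of a ramp lags by at most one window's drift
  expect_true(all(abs(bl - ramp_vals) <= 0.2 * 50 + 1e-9))

  sim <- simulate_calcium_trace(duration_min = 960, drift_slope = 0.05,
                                spike_rate_per_min = 0.02, noise_sd = 5,
                                seed = 31)
  est <- estimate_baseline(sim$trace)
  truth <- 100 + 0.05 * sim$trace$times_min
  rmse <- sqrt(mean((est - truth)^2))
  expect_lt(rmse, 5 + 0.05 * 50)   # noise_sd + 5% of mean spike amplitude
  # lower envelope: baseline stays at or below the trace almost everywhere
  expect_gte(mean(sim$trace$values >= est), 0.85)

  expect_error(estimate_baseline(flat, window_min = 1), "two sampling")
  expect_error(estimate_baseline(flat, window_min = 1e4), "span")
})

test_that("spike detection handles flat traces and resolves programmed spikes", {
  flat <- calcium_trace(seq(0, 500, by = 2.5), rep(7, 201))
  sp0 <- detect_spikes(flat)
  expect_length(sp0$peak_times_min, 0)
  expect_length(sp0$intervals_min, 0)

  sim <- simulate_calcium_trace(duration_min = 960,
                                spike_times = c(100, 125),
                                spike_amplitudes = c(50, 60), noise_sd = 0,
                                decay_tau_min = 5)
  sp <- detect_spikes(sim$trace)
  expect_equal(sp$peak_times_min, c(100, 125))
  expect_equal(sp$intervals_min, 25)
  expect_equal(sp$heights, c(50, 60 + 50 * exp(-5)), tolerance = 0.05)
})

test_that("detection recall, precision and heights hold against generator truth", {
  tp_r <- 0; n_t <- 0; tp_p <- 0; n_d <- 0
  height_errs <- c()
  for (i in 1:20) {
    sim <- simulate_calcium_trace(duration_min = 960, dt_min = 2.5,
                                  spike_rate_per_min = 0.02,
                                  amplitude_mean = 50, noise_sd = 5,
                                  seed = 400 + i)
    sp <- detect_spikes(sim$trace)
    m <- spike_match(sp$peak_times_min, sim$truth$sampled_peak_times_min,
                     tol = 2.5 + 1e-9)
    tp_r <- tp_r + m$tp_recall; n_t <- n_t + m$n_truth
    tp_p <- tp_p + m$tp_precision; n_d <- n_d + m$n_det
    for (j in seq_along(sim$truth$sampled_peak_times_min)) {
      hit <- which.min(abs(sp$peak_times_min - sim$truth$sampled_peak_times_min[j]))
      if (length(hit) && abs(sp$peak_times_min[hit] -
                             sim$truth$sampled_peak_times_min[j]) <= 2.5 + 1e-9)
        height_errs <- c(height_errs,
                         abs(sp$heights[hit] - sim$truth$sampled_heights[j]) /
                           sim$truth$sampled_heights[j])
    }
  }
  expect_gte(tp_r / n_t, 0.95)
  expect_gte(tp_p / n_d, 0.95)
  expect_lt(median(height_errs), 0.10)
})

test_that("interval identity and shift/scale invariances hold", {
  sim <- simulate_calcium_trace(duration_min = 960, spike_rate_per_min = 0.02,
                                noise_sd = 5, seed = 55)
  sp <- detect_spikes(sim$trace)
  expect_gt(length(sp$peak_times_min), 0)
  expect_length(sp$intervals_min, length(sp$peak_times_min) - 1)

  # time shift moves peak times, leaves heights and intervals unchanged
  shifted <- calcium_trace(sim$trace$times_min + 500, sim$trace$values)
  sps <- detect_spikes(shifted)
  expect_equal(sps$peak_times_min, sp$peak_times_min + 500)
  expect_equal(sps$heights, sp$heights)
  expect_equal(sps$intervals_min, sp$intervals_min)

  # amplitude scaling scales heights, leaves times and intervals unchanged
  scaled <- calcium_trace(sim$trace$times_min, sim$trace$values * 3)
  spk <- detect_spikes(scaled)
  expect_equal(spk$peak_times_min, sp$peak_times_min)
  expect_equal(spk$heights, sp$heights * 3, tolerance = 1e-9)
})

test_that("group comparison detects amplitude and rate differences", {
  mk_group <- function(label, amp, rate, n, seed0) {
    lapply(seq_len(n), function(i)
      detect_spikes(simulate_calcium_trace(
        duration_min = 960, spike_rate_per_min = rate, amplitude_mean = amp,
        noise_sd = 5, seed = seed0 + i, embryo_id = sprintf("%s_%d", label, i),
        treatment = label)$trace))
  }
  ctrl <- mk_group("control", amp = 50, rate = 0.02, n = 3, seed0 = 600)
  loud <- mk_group("doubled", amp = 100, rate = 0.02, n = 3, seed0 = 700)
  fast <- mk_group("fast", amp = 50, rate = 0.04, n = 3, seed0 = 800)

  cmp <- compare_spike_groups(c(ctrl, loud))
  expect_lt(cmp$height$anova$p, 0.01)
  cmp2 <- compare_spike_groups(c(ctrl, fast))
  expect_lt(cmp2$interval$tukey$p_adj[1], 0.05)

  # a treatment with < 2 events is excluded with a warning
  empty <- detect_spikes(calcium_trace(seq(0, 500, 2.5), rep(1, 201)))
  empty$treatment <- "silent"
  w <- capture_warnings(cmp3 <- compare_spike_groups(c(ctrl, loud, list(empty))))
  expect_true(any(grepl("silent", w)))
  expect_false("silent" %in% c(cmp3$height$tukey$group1, cmp3$height$tukey$group2))
})

test_that("traces round-trip through long and wide CSV", {
  sim1 <- simulate_calcium_trace(duration_min = 100, spike_times = 50,
                                 spike_amplitudes = 40, noise_sd = 1, seed = 2,
                                 embryo_id = "a", treatment = "ctrl")
  sim2 <- simulate_calcium_trace(duration_min = 100, spike_times = 25,
                                 spike_amplitudes = 40, noise_sd = 1, seed = 3,
                                 embryo_id = "b", treatment = "ctrl")
  long <- rbind(
    data.frame(time_min = sim1$trace$times_min, value = sim1$trace$values,
               embryo_id = "a", treatment = "ctrl"),
    data.frame(time_min = sim2$trace$times_min, value = sim2$trace$values,
               embryo_id = "b", treatment = "ctrl"))
  f1 <- withr::local_tempfile(fileext = ".csv")
  write.csv(long, f1, row.names = FALSE)
  traces <- read_traces_csv(f1)
  expect_length(traces, 2)
  expect_equal(traces[["a"]]$values, sim1$trace$values)

  wide <- data.frame(time_min = sim1$trace$times_min, a = sim1$trace$values,
                     b = sim2$trace$values)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(wide, f2, row.names = FALSE)
  traces2 <- read_traces_csv(f2, treatment = "ctrl")
  expect_equal(traces2[["b"]]$values, sim2$trace$values)
})
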