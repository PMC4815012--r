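# small geometry keeps per-test image work cheap; quarter-scale defaults are
# exercised in the intensity-recovery suite
small_geom <- function() {
  image_geometry(width_px = 120L, height_px = 90L, pixel_spacing_um = 1.28,
                 trunk_halfwidth_px = 14L, notochord_halfwidth_px = 3L)
}

small_config <- function(...) run_config(roi_radius_px = 30, ...)

# quantify a set of programmed folds through the full image pipeline and
# return measured fold inductions (normalised against the fold-1 controls)
measure_folds <- function(folds, doses, n_per_fold = 1, noise_sd = 0,
                          geometry = small_geom(), config = small_config(),
                          seed = 1L) {
  stopifnot(length(folds) == length(doses), doses[1] == 0, folds[1] == 1)
  meta <- NULL
  images <- list()
  k <- 0L
  for (i in seq_along(folds)) {
    for (r in seq_len(n_per_fold)) {
      k <- k + 1L
      id <- sprintf("e%03d", k)
      images[[id]] <- simulate_embryo_image(geometry, fold = folds[i],
                                            noise_sd = noise_sd,
                                            seed = seed + k)$image
      meta <- rbind(meta, data.frame(embryo_id = id, chemical = "chemX",
                                     concentration_uM = doses[i],
                                     group = if (doses[i] == 0) "control" else "treated"))
    }
  }
  rec <- quantify_batch(meta, images = images, config = config)
  normalise_records(rec)
}

# non-exclusive truth/detection matching within a time tolerance
spike_match <- function(detected_times, truth_times, tol) {
  recall_hits <- vapply(truth_times, function(tt)
    any(abs(detected_times - tt) <= tol), logical(1))
  precision_hits <- vapply(detected_times, function(dt)
    any(abs(truth_times - dt) <= tol), logical(1))
  list(n_truth = length(truth_times), n_det = length(detected_times),
       tp_recall = sum(recall_hits), tp_precision = sum(precision_hits))
}

# upper-tail studentized range probability by direct double quadrature,
# independent of stats::ptukey
ptukey_quadrature <- function(q0, k, df) {
  range_cdf <- function(w) {
    stats::integrate(function(z)
      k * stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - w))^(k - 1),
      -Inf, Inf, rel.tol = 1e-11)$value
  }
  s_density <- function(s)
    2 * (df / 2)^(df / 2) / gamma(df / 2) * s^(df - 1) * exp(-df * s^2 / 2)
  cdf <- stats::integrate(function(s)
    vapply(s, function(si) s_density(si) * range_cdf(q0 * si), numeric(1)),
    0, Inf, rel.tol = 1e-9)$value
  1 - cdf
}
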