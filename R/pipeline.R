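#' Pipeline configuration
#'
#' Collects the tunable stage parameters in one object. Defaults follow the
#' acquisition-scale protocol where one exists: smoothing sigma 10 px, ROI
#' radius 350 px, ANOVA gate alpha 0.001, effect level 1.5-fold, trace
#' sampling 2.5 min; the spike-detection settings (k_mad 3, window 50 min)
#' are the package's own documented defaults.
#'
#' @param sigma_px Gaussian smoothing sigma in pixels.
#' @param roi_radius_px ROI disc radius in pixels.
#' @param gray_mode RGB-to-gray mode: `"luma"` or `"green"`.
#' @param background_mode ROI background estimate: `"modal"` or `"min"`.
#' @param alpha ANOVA gate significance threshold.
#' @param effect_level Target fold induction for the EC estimate.
#' @param fallback Model fallback policy: `"linear"` (fall back when the
#'   Gaussian fit fails or yields no valid EC), `"none"` (Gaussian fit
#'   failure only), or `"force_linear"` (always use the linear model).
#' @param k_mad Spike detection threshold in noise scales.
#' @param window_min Baseline window in minutes.
#' @param dt_min Trace sampling interval in minutes.
#' @param seed Default seed for the simulation stages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sigma_px = 10, roi_radius_px = 350,
                       gray_mode = "luma", background_mode = "modal",
                       alpha = 0.001, effect_level = 1.5,
                       fallback = "linear", k_mad = 3, window_min = 50,
                       dt_min = 2.5, seed = 1L) {
  structure(list(sigma_px = sigma_px, roi_radius_px = roi_radius_px,
                 gray_mode = gray_mode, background_mode = background_mode,
                 alpha = alpha, effect_level = effect_level,
                 fallback = fallback, k_mad = k_mad, window_min = window_min,
                 dt_min = dt_min, seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a [run_config()] equal to the one written.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the full synthetic demo pipeline
#'
#' End-to-end reproducible run: simulates dose series for an inducing
#' chemical (peaked concentration-response, peak fold `d = 2.5`) and an
#' inert one (flat response), quantifies every image, analyses both
#' chemicals (ANOVA gate, model fit, EC1.5), simulates control and treated
#' calcium traces and compares spike statistics, then writes all artifacts
#' (records CSV, per-chemical report JSON, spikes CSV, comparison JSON) plus
#' a manifest with parameters, seed and an MD5 checksum for every output
#' file.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed; reruns with the same seed give byte-identical
#'   artifacts.
#' @param config A [run_config()]; `roi_radius_px` should match the image
#'   geometry (87 for the default quarter-scale simulation).
#' @param n_per_dose Embryos per dose.
#' @param n_traces_per_group Calcium traces per treatment group.
#' @param geometry [image_geometry()] used for the simulated images.
#' @return Invisibly, a list with the two `chemical_report`s, the spike
#'   comparison, and the manifest.
#' @export
run_demo <- function(out_dir, seed = 1L,
                     config = run_config(roi_radius_px = 87),
                     n_per_dose = 10, n_traces_per_group = 4,
                     geometry = image_geometry()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  doses <- c(0, 0.3, 1, 3, 10, 30)
  inducer_model <- gaussian_cr_model(b = 0.8, d = 2.5, e = 5)
  flat_model <- gaussian_cr_model(b = 0.8, d = 1, e = 5)

  bundles <- list(
    inducerA = simulate_dose_series(doses, inducer_model,
                                    n_per_dose = n_per_dose,
                                    fold_noise_sd = 0.1, pixel_noise_sd = 5,
                                    geometry = geometry, chemical = "inducerA",
                                    seed = seed),
    inertB = simulate_dose_series(doses, flat_model, n_per_dose = n_per_dose,
                                  fold_noise_sd = 0.1, pixel_noise_sd = 5,
                                  geometry = geometry, chemical = "inertB",
                                  seed = seed + 1L))
  records <- do.call(rbind, lapply(names(bundles), function(nm)
    quantify_batch(bundles[[nm]]$metadata, images = bundles[[nm]]$images,
                   config = config)))
  rec_csv <- file.path(out_dir, "records.csv")
  utils::write.csv(records, rec_csv, row.names = FALSE)

  reports <- lapply(names(bundles), function(nm)
    analyze_chemical(records, chemical = nm, config = config,
                     out_json = file.path(out_dir, paste0("report_", nm, ".json"))))
  names(reports) <- names(bundles)

  # calcium traces: control vs a treatment with larger, more frequent spikes
  trace_sets <- list()
  for (i in seq_len(n_traces_per_group)) {
    trace_sets[[length(trace_sets) + 1L]] <- simulate_calcium_trace(
      spike_rate_per_min = 0.02, amplitude_mean = 50, noise_sd = 5,
      seed = seed + 100L + i, embryo_id = sprintf("ctrl_%d", i),
      treatment = "control")$trace
    trace_sets[[length(trace_sets) + 1L]] <- simulate_calcium_trace(
      spike_rate_per_min = 0.04, amplitude_mean = 100, noise_sd = 5,
      seed = seed + 200L + i, embryo_id = sprintf("trt_%d", i),
      treatment = "treated")$trace
  }
  spike_sets <- lapply(trace_sets, detect_spikes, k_mad = config$k_mad,
                       window_min = config$window_min)
  spikes_csv <- file.path(out_dir, "spikes.csv")
  utils::write.csv(spikes_table(spike_sets), spikes_csv, row.names = FALSE)
  comparison <- compare_spike_groups(spike_sets)
  jsonlite::write_json(
    list(height = comparison$height, interval = comparison$interval),
    file.path(out_dir, "spike_comparison.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null")

  cfg_path <- file.path(out_dir, "config.yaml")
  write_run_config(config, cfg_path)
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    seed = seed,
    parameters = unclass(config),
    n_per_dose = n_per_dose, doses = doses,
    n_traces_per_group = n_traces_per_group,
    files = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(file.path(out_dir, f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(reports = reports, spike_comparison = comparison,
                 manifest = manifest))
}
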