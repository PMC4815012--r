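#' Estimate the slow baseline of a calcium trace
#'
#' Running lower-envelope estimate: the 10th percentile of the trace over a
#' centred window (default 50 minutes), edge-handled by shrinking the window
#' at the trace ends. The low percentile makes the estimate insensitive to
#' sparse positive-going spikes while following slow drift.
#'
#' @param trace A [calcium_trace()].
#' @param window_min Window length in minutes (>= 2 sampling intervals).
#' @param prob Percentile used for the envelope (default 0.1).
#' @return Numeric baseline series, same length as the trace.
#' @export
estimate_baseline <- function(trace, window_min = 50, prob = 0.1) {
  stopifnot(inherits(trace, "calcium_trace"))
  dt <- trace$dt_min
  if (window_min < 2 * dt)
    stop("window must span at least two sampling intervals", call. = FALSE)
  span <- diff(range(trace$times_min))
  if (window_min > span)
    stop("window larger than the trace span", call. = FALSE)
  width <- max(3L, round(window_min / dt))
  if (width %% 2L == 0L) width <- width + 1L
  as.numeric(zoo::rollapply(zoo::zoo(trace$values), width = width,
                            FUN = stats::quantile, probs = prob, names = FALSE,
                            align = "center", partial = TRUE))
}

#' Detect calcium spikes in a trace
#'
#' Baseline-subtracted, MAD-thresholded local-maximum detection:
#' `dF = trace - baseline` is recentred by its median (a robust zero, since
#' spikes are sparse), and spikes are strict local maxima of `dF` exceeding
#' `k_mad` noise scales, separated by at least `min_separation` samples
#' (enforced greedily in order of decreasing height). Peaks at the first or
#' last sample are excluded. Heights are `dF` at the peak; intervals are the
#' differences of adjacent peak times.
#'
#' The noise scale is `1.4826 x MAD / sqrt(2)` of the first differences of
#' `dF`: differencing removes the slowly decaying transient tails that would
#' otherwise inflate a direct MAD of `dF` at high spike rates. A candidate
#' peak must also *rise* by more than the threshold above the lowest of the
#' two preceding samples; an exponentially decaying transient satisfies this
#' trivially at its onset, whereas noise bumps riding on the elevated tail
#' of an earlier spike do not, which is what distinguishes a new spike from
#' an echo of the last one.
#'
#' @param trace A [calcium_trace()].
#' @param k_mad Detection threshold in noise scales (default 3).
#' @param min_separation Minimum peak separation in samples (default 1).
#' @param window_min Baseline window passed to [estimate_baseline()].
#' @return A list of class `spike_set`: `peak_times_min`, `heights`,
#'   `intervals_min`, `baseline`, `noise_scale`, `threshold`, `embryo_id`,
#'   `treatment`.
#' @export
detect_spikes <- function(trace, k_mad = 3, min_separation = 1,
                          window_min = 50) {
  stopifnot(inherits(trace, "calcium_trace"))
  if (k_mad <= 0) stop("k_mad must be positive", call. = FALSE)
  baseline <- estimate_baseline(trace, window_min = window_min)
  dF <- trace$values - baseline
  dF <- dF - stats::median(dF)
  noise <- stats::mad(diff(dF)) / sqrt(2)   # 1.4826 x MAD of differences
  # floor keeps numerically-flat traces (noise scale ~ 0) from turning
  # round-off ripples into spikes
  thr <- max(k_mad * noise, 1e-8 * diff(range(trace$values)))
  n <- length(dF)
  v <- dF
  cand <- which(v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
  cand <- cand[v[cand] > thr]
  # onset-rise criterion: reject noise bumps riding a decaying tail
  rise <- vapply(cand, function(i)
    v[i] - min(v[max(1L, i - 2L):(i - 1L)]), numeric(1))
  cand <- cand[rise > thr]
  # greedy suppression by descending height
  keep <- integer(0)
  for (i in cand[order(v[cand], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(keep - i) >= min_separation))
      keep <- c(keep, i)
  }
  keep <- sort(keep)
  pk_t <- trace$times_min[keep]
  structure(list(
    peak_times_min = pk_t,
    heights = v[keep],
    intervals_min = if (length(pk_t) > 1) diff(pk_t) else numeric(0),
    baseline = baseline, noise_scale = noise, threshold = thr,
    embryo_id = trace$embryo_id, treatment = trace$treatment
  ), class = "spike_set")
}

#' @export
print.spike_set <- function(x, ...) {
  cat(sprintf("<spike_set> %s (%s): %d spikes, threshold %.3g\n",
              x$embryo_id, x$treatment, length(x$peak_times_min), x$threshold))
  invisible(x)
}

#' Pool spike sets into a tidy event table
#'
#' @param spike_sets List of `spike_set` objects.
#' @return Data.frame with one row per spike: `embryo_id`, `treatment`,
#'   `peak_time_min`, `height`, `interval_to_next_min` (NA for each embryo's
#'   last spike).
#' @export
spikes_table <- function(spike_sets) {
  rows <- lapply(spike_sets, function(s) {
    np <- length(s$peak_times_min)
    if (np == 0) return(NULL)
    data.frame(embryo_id = s$embryo_id, treatment = s$treatment,
               peak_time_min = s$peak_times_min, height = s$heights,
               interval_to_next_min = c(s$intervals_min, NA_real_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(embryo_id = character(), treatment = character(),
                      peak_time_min = numeric(), height = numeric(),
                      interval_to_next_min = numeric())
  out
}

#' Compare spike heights and intervals between treatments
#'
#' Spikes are pooled across embryos within each treatment (event-level
#' pooling) and the treatments compared by one-way ANOVA followed by Tukey
#' HSD, separately for spike heights and for adjacent-spike intervals.
#' Treatments contributing fewer than two events to a measure are excluded
#' from that comparison with a warning.
#'
#' @param spike_sets List of `spike_set` objects (several per treatment is
#'   expected).
#' @return A list with elements `height` and `interval`, each a list
#'   `anova` (see [anova_gate()] internals) and `tukey` (see [tukey_hsd()]),
#'   plus the pooled event table `events`.
#' @export
compare_spike_groups <- function(spike_sets) {
  ev <- spikes_table(spike_sets)
  all_treatments <- unique(vapply(spike_sets, `[[`, "", "treatment"))
  compare_one <- function(values, groups, what) {
    keep_tab <- table(groups[!is.na(values)])
    ok <- names(keep_tab)[keep_tab >= 2]
    drop <- setdiff(all_treatments, ok)
    if (length(drop))
      warning(sprintf("treatment(s) %s excluded from %s comparison (< 2 events)",
                      paste(drop, collapse = ", "), what), call. = FALSE)
    sel <- groups %in% ok & !is.na(values)
    if (length(ok) < 2) return(NULL)
    list(anova = one_way_anova(values[sel], groups[sel]),
         tukey = tukey_hsd(values[sel], groups[sel]))
  }
  list(height = compare_one(ev$height, ev$treatment, "height"),
       interval = compare_one(ev$interval_to_next_min, ev$treatment, "interval"),
       events = ev)
}

#' Read calcium traces from CSV
#'
#' Long format: columns `time_min`, `value` and optionally `embryo_id` and
#' `treatment`; one trace per embryo_id. Wide format (`time_min` plus one
#' column per embryo) is also accepted, with the column name used as
#' embryo_id.
#'
#' @param path CSV path.
#' @param treatment Default treatment label when the file has none.
#' @return List of [calcium_trace()] objects.
#' @export
read_traces_csv <- function(path, treatment = "control") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_min" %in% names(df)) stop("CSV needs a time_min column", call. = FALSE)
  if ("value" %in% names(df)) {
    if (!"embryo_id" %in% names(df)) df$embryo_id <- "embryo1"
    if (!"treatment" %in% names(df)) df$treatment <- treatment
    lapply(split(df, df$embryo_id), function(d)
      calcium_trace(d$time_min, d$value, embryo_id = d$embryo_id[1],
                    treatment = d$treatment[1]))
  } else {
    ids <- setdiff(names(df), "time_min")
    if (!length(ids)) stop("no trace columns found", call. = FALSE)
    lapply(stats::setNames(ids, ids), function(id)
      calcium_trace(df$time_min, df[[id]], embryo_id = id,
                    treatment = treatment))
  }
}
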