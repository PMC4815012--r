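#' Convert an embryo image to grayscale
#'
#' Single-channel images pass through unchanged. RGB images are combined
#' with the standard luma weights (0.2989, 0.5870, 0.1140) by default; the
#' `"green"` mode keeps only the green channel, which can be preferable for a
#' GFP reporter where the other channels carry no signal.
#'
#' @param image An [embryo_image()] with 1 or 3 channels.
#' @param mode `"luma"` (default) or `"green"`.
#' @return A single-channel [embryo_image()].
#' @export
to_grayscale <- function(image, mode = c("luma", "green")) {
  mode <- match.arg(mode)
  stopifnot(inherits(image, "embryo_image"))
  if (image$channels == 1L) return(image)
  if (image$channels != 3L) stop("channel count must be 1 or 3", call. = FALSE)
  p <- image$pixels
  gray <- if (mode == "green") p[, , 2] else
    0.2989 * p[, , 1] + 0.5870 * p[, , 2] + 0.1140 * p[, , 3]
  embryo_image(gray, image$pixel_spacing_um)
}

# 1-D Gaussian smoothing operator with mirror boundary, built as an n x n
# matrix so that smoothing is Kr %*% X %*% t(Kc). The kernel is truncated at
# 5 sigma and renormalised; operators are memoised on (n, sigma).
gaussian_operator <- function(n, sigma) {
  key <- sprintf("gop_%d_%.10g", n, sigma)
  cached <- .musclescreen_cache[[key]]
  if (!is.null(cached)) return(cached)
  r <- ceiling(5 * sigma)
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  i <- seq_len(n)
  for (o in seq_along(w)) {
    j <- i + (o - r - 1L)
    # mirror (symmetric) reflection at both edges
    j <- ifelse(j < 1L, 1L - j, j)
    j <- ifelse(j > n, 2L * n + 1L - j, j)
    # a 5-sigma kernel can overshoot twice on tiny images
    j <- ifelse(j < 1L, 1L - j, j)
    j <- ifelse(j > n, 2L * n + 1L - j, j)
    idx <- (j - 1L) * n + i
    K[idx] <- K[idx] + w[o]
  }
  .musclescreen_cache[[key]] <- K
  K
}

#' Gaussian-smooth an image
#'
#' Separable convolution with a normalised Gaussian kernel (truncated at
#' 5 sigma) and mirror boundary handling. Used only to localise the region
#' of interest; intensity statistics are always taken from the unsmoothed
#' image.
#'
#' @param image A single-channel [embryo_image()].
#' @param sigma_px Kernel standard deviation in pixels (default 10, the
#'   acquisition-scale setting).
#' @return The smoothed [embryo_image()], same size as the input.
#' @export
smooth_image <- function(image, sigma_px = 10) {
  stopifnot(inherits(image, "embryo_image"))
  if (image$channels != 1L) stop("smooth_image needs a single channel", call. = FALSE)
  if (sigma_px <= 0) stop("sigma_px must be positive", call. = FALSE)
  X <- image$pixels
  Kr <- gaussian_operator(nrow(X), sigma_px)
  Kc <- gaussian_operator(ncol(X), sigma_px)
  embryo_image(pmax(Kr %*% X %*% t(Kc), 0), image$pixel_spacing_um)
}

# modal intensity via a 256-bin histogram (background estimate for roughly
# constant backgrounds)
modal_intensity <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = 257L)
  counts <- tabulate(findInterval(v, br, rightmost.closed = TRUE), 256L)
  mid <- (br[-1] + br[-257]) / 2
  mid[which.max(counts)]
}

#' Extract a disc region of interest around the embryo trunk
#'
#' The ROI centre is the intensity-weighted centroid of the smoothed image
#' after background subtraction (background = modal intensity, i.e. the most
#' common smoothed value, which for a mostly-empty field is the background
#' level). The mask is a disc of the given radius, clipped at the image
#' borders.
#'
#' @param smoothed A smoothed single-channel [embryo_image()].
#' @param radius_px ROI radius in pixels (default 350, the acquisition-scale
#'   setting; use ~87 for quarter-scale synthetic images).
#' @param background_mode `"modal"` (default) or `"min"`.
#' @return An object of class `roi_mask`: logical matrix `mask`, `center`
#'   `(row, col)`, `radius_px`, `background`.
#' @export
extract_roi <- function(smoothed, radius_px = 350,
                        background_mode = c("modal", "min")) {
  background_mode <- match.arg(background_mode)
  stopifnot(inherits(smoothed, "embryo_image"))
  if (smoothed$channels != 1L) stop("extract_roi needs a single channel", call. = FALSE)
  radius_px <- as.integer(radius_px)
  if (radius_px < 1L) stop("radius_px must be >= 1", call. = FALSE)
  X <- smoothed$pixels
  bg <- if (background_mode == "min") min(X) else modal_intensity(X)
  S <- pmax(X - bg, 0)
  tot <- sum(S)
  if (tot <= 1e-10 * length(S) * max(1e-12, max(abs(X))))
    stop("no signal above background; cannot place ROI", call. = FALSE)
  h <- nrow(X); w <- ncol(X)
  row_w <- rowSums(S); col_w <- colSums(S)
  center <- c(sum(row_w * seq_len(h)) / tot, sum(col_w * seq_len(w)) / tot)
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  mask <- (rr - center[1])^2 + (cc - center[2])^2 <= radius_px^2
  if (!any(mask)) stop("ROI mask is empty", call. = FALSE)
  structure(list(mask = mask, center = center, radius_px = radius_px,
                 background = bg),
            class = "roi_mask")
}

#' Intensity statistics over a region of interest
#'
#' Computes the global statistics (minimum, maximum, median, mean, sample
#' standard deviation, pixel count) over the ORIGINAL, unsmoothed pixel
#' values inside the mask. The masked pixels are flattened into a 1-D sample
#' before the order statistics; the median uses the midpoint convention for
#' even counts, the standard deviation the n-1 denominator.
#'
#' @param original The unsmoothed single-channel [embryo_image()].
#' @param roi An `roi_mask` from [extract_roi()], or any logical matrix of
#'   the same size.
#' @return A one-row data.frame: `n_pixels`, `min`, `max`, `median`, `mean`,
#'   `sd`.
#' @export
summarize_roi <- function(original, roi) {
  stopifnot(inherits(original, "embryo_image"))
  if (original$channels != 1L) stop("summarize_roi needs a single channel", call. = FALSE)
  mask <- if (inherits(roi, "roi_mask")) roi$mask else roi
  if (!is.logical(mask) || !identical(dim(mask), dim(original$pixels)))
    stop("mask must be a logical matrix matching the image", call. = FALSE)
  v <- original$pixels[mask]
  if (length(v) == 0L) stop("empty mask", call. = FALSE)
  data.frame(n_pixels = length(v), min = min(v), max = max(v),
             median = stats::median(v), mean = mean(v),
             sd = if (length(v) > 1L) stats::sd(v) else 0)
}

#' Read an embryo image from TIFF or PNG
#'
#' 16-bit grayscale TIFFs written by [write_embryo_image()] round-trip to
#' integer intensities; PNG and float TIFFs come back on their native scale.
#' Absolute scale does not matter downstream because fold induction is
#' normalised to the solvent-control mean.
#'
#' @param path File path (`.tif`/`.tiff` or `.png`).
#' @param pixel_spacing_um Pixel spacing to record on the image.
#' @return An [embryo_image()].
#' @export
read_embryo_image <- function(path, pixel_spacing_um = 0.32) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  p <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
    png = png::readPNG(path) * 255,
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(p)) == 3L && dim(p)[3] == 4L) p <- p[, , 1:3]  # drop alpha
  if (length(dim(p)) == 3L && dim(p)[3] == 1L) p <- p[, , 1]
  embryo_image(p, pixel_spacing_um)
}

#' Write an embryo image as 16-bit grayscale TIFF
#'
#' @param image A single-channel [embryo_image()].
#' @param path Output path.
#' @param max_intensity Intensity mapped to 65535; brighter pixels are
#'   clipped.
#' @return Invisibly, `path`.
#' @export
write_embryo_image <- function(image, path, max_intensity = 1000) {
  stopifnot(inherits(image, "embryo_image"), image$channels == 1L)
  scaled <- pmin(pmax(image$pixels / max_intensity, 0), 1)
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  invisible(path)
}

#' Quantify a batch of embryo images
#'
#' Runs the per-embryo pipeline (grayscale conversion, Gaussian smoothing,
#' ROI extraction, intensity statistics on the original pixels) over a
#' metadata table and returns one record per embryo. Images are taken from
#' an in-memory list (`images`, as produced by [simulate_dose_series()]) or
#' read from the paths in `metadata$image_path`. Rows whose image cannot be
#' processed are skipped with a warning and counted in the
#' `n_failed` attribute.
#'
#' @param metadata Data.frame with columns `embryo_id`, `chemical`,
#'   `concentration_uM`, `group` and, when `images` is `NULL`, `image_path`.
#' @param images Optional named list of [embryo_image()] keyed by embryo_id.
#' @param config A [run_config()]; `sigma_px`, `roi_radius_px`, `gray_mode`
#'   and `background_mode` are used here.
#' @param tissue_masks Optional list of logical matrices (e.g. the `masks`
#'   element of synthetic truth); each mask adds `<name>_mean` etc. columns.
#' @param out_csv Optional path; when given the records are also written as
#'   CSV.
#' @return Data.frame of intensity records, one row per embryo.
#' @export
quantify_batch <- function(metadata, images = NULL, config = run_config(),
                           tissue_masks = NULL, out_csv = NULL) {
  need <- c("embryo_id", "chemical", "concentration_uM", "group")
  if (!all(need %in% names(metadata)))
    stop("metadata must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (is.null(images) && !"image_path" %in% names(metadata))
    stop("supply in-memory images or an image_path column", call. = FALSE)
  out <- vector("list", nrow(metadata))
  n_failed <- 0L
  for (i in seq_len(nrow(metadata))) {
    row <- metadata[i, ]
    rec <- tryCatch({
      img <- if (!is.null(images)) images[[row$embryo_id]] else
        read_embryo_image(row$image_path)
      if (is.null(img)) stop("no image for embryo ", row$embryo_id)
      gray <- to_grayscale(img, mode = config$gray_mode)
      sm <- smooth_image(gray, sigma_px = config$sigma_px)
      roi <- extract_roi(sm, radius_px = config$roi_radius_px,
                         background_mode = config$background_mode)
      s <- summarize_roi(gray, roi)
      rec <- cbind(row[need], s, row.names = NULL)
      if (!is.null(tissue_masks)) {
        for (tn in names(tissue_masks)) {
          ts <- summarize_roi(gray, tissue_masks[[tn]])
          names(ts) <- paste0(tn, "_", names(ts))
          rec <- cbind(rec, ts)
        }
      }
      rec
    }, error = function(e) {
      warning(sprintf("embryo %s skipped: %s", row$embryo_id, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(rec)) n_failed <- n_failed + 1L else out[[i]] <- rec
  }
  records <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  attr(records, "n_failed") <- n_failed
  if (!is.null(out_csv)) utils::write.csv(records, out_csv, row.names = FALSE)
  records
}
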