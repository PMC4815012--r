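#' Synthetic embryo image geometry
#'
#' Describes the layout of a rendered embryo trunk inside a synthetic
#' micrograph. The default geometry is a quarter-scale version of the native
#' acquisition frame (1392 x 1040 px at 0.32 um/px), i.e. 348 x 260 px at
#' 1.28 um/px, which keeps test runtimes short; pass `width_px = 1392,
#' height_px = 1040, pixel_spacing_um = 0.32` for full-scale images.
#'
#' @param width_px,height_px Image size in pixels.
#' @param pixel_spacing_um Physical pixel spacing in micrometres.
#' @param trunk_center `(row, col)` of the trunk centre; defaults to the
#'   image centre.
#' @param trunk_length_px Length of the rendered trunk along the column axis.
#' @param trunk_halfwidth_px Half-width of the trunk band along the row axis.
#' @param notochord_halfwidth_px Half-width of the notochord band; must be
#'   smaller than `trunk_halfwidth_px`.
#' @param n_somite_stripes Number of chevron muscle stripes along the trunk.
#' @return An object of class `image_geometry`.
#' @export
image_geometry <- function(width_px = 348L, height_px = 260L,
                           pixel_spacing_um = 1.28,
                           trunk_center = NULL,
                           trunk_length_px = NULL,
                           trunk_halfwidth_px = NULL,
                           notochord_halfwidth_px = NULL,
                           n_somite_stripes = 8L) {
  width_px <- as.integer(width_px)
  height_px <- as.integer(height_px)
  if (width_px < 8L || height_px < 8L)
    stop("image must be at least 8 x 8 px", call. = FALSE)
  if (pixel_spacing_um <= 0) stop("pixel_spacing_um must be positive", call. = FALSE)
  if (is.null(trunk_center)) trunk_center <- c(height_px / 2, width_px / 2)
  if (is.null(trunk_length_px)) trunk_length_px <- round(0.7 * width_px)
  if (is.null(trunk_halfwidth_px)) trunk_halfwidth_px <- round(0.15 * height_px)
  if (is.null(notochord_halfwidth_px))
    notochord_halfwidth_px <- max(1L, round(trunk_halfwidth_px / 5))
  g <- structure(list(
    width_px = width_px, height_px = height_px,
    pixel_spacing_um = pixel_spacing_um,
    trunk_center = as.numeric(trunk_center),
    trunk_length_px = as.integer(trunk_length_px),
    trunk_halfwidth_px = as.integer(trunk_halfwidth_px),
    notochord_halfwidth_px = as.integer(notochord_halfwidth_px),
    n_somite_stripes = as.integer(n_somite_stripes)
  ), class = "image_geometry")
  validate_geometry(g)
  g
}

validate_geometry <- function(g) {
  r0 <- g$trunk_center[1]; c0 <- g$trunk_center[2]
  if (g$notochord_halfwidth_px >= g$trunk_halfwidth_px)
    stop("notochord_halfwidth_px must be smaller than trunk_halfwidth_px",
         call. = FALSE)
  if (g$n_somite_stripes < 0) stop("n_somite_stripes must be >= 0", call. = FALSE)
  if (r0 - g$trunk_halfwidth_px < 1 || r0 + g$trunk_halfwidth_px > g$height_px ||
      c0 - g$trunk_length_px / 2 < 1 || c0 + g$trunk_length_px / 2 > g$width_px)
    stop("trunk exceeds image bounds", call. = FALSE)
  invisible(g)
}

#' Embryo image container
#'
#' A thin container for a single micrograph: a 2-D intensity matrix (one
#' channel) or a `height x width x 3` array (RGB), plus the physical pixel
#' spacing.
#'
#' @param pixels Numeric matrix (grayscale) or 3-slice array (RGB);
#'   intensities must be non-negative.
#' @param pixel_spacing_um Pixel spacing in micrometres (native acquisition:
#'   0.32).
#' @return An object of class `embryo_image` with elements `pixels`,
#'   `pixel_spacing_um`, `channels`.
#' @export
embryo_image <- function(pixels, pixel_spacing_um = 0.32) {
  if (is.matrix(pixels)) {
    channels <- 1L
  } else if (is.array(pixels) && length(dim(pixels)) == 3L && dim(pixels)[3] == 3L) {
    channels <- 3L
  } else {
    stop("pixels must be a matrix or a height x width x 3 array", call. = FALSE)
  }
  if (length(pixels) == 0L) stop("empty image", call. = FALSE)
  if (any(pixels < 0)) stop("negative intensities not allowed", call. = FALSE)
  structure(list(pixels = pixels, pixel_spacing_um = pixel_spacing_um,
                 channels = channels),
            class = "embryo_image")
}

#' @export
print.embryo_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<embryo_image> %d x %d px, %d channel(s), %.3g um/px\n",
              d[1], d[2], x$channels, x$pixel_spacing_um))
  invisible(x)
}

# tissue masks for a geometry: trunk band, notochord band, chevron muscle
# stripes (stripes and notochord are disjoint; both are subsets of the trunk)
render_tissue_masks <- function(g) {
  h <- g$height_px; w <- g$width_px
  r0 <- g$trunk_center[1]; c0 <- g$trunk_center[2]
  row <- matrix(seq_len(h), h, w)
  col <- matrix(seq_len(w), h, w, byrow = TRUE)
  trunk <- abs(row - r0) <= g$trunk_halfwidth_px &
    abs(col - c0) <= g$trunk_length_px / 2
  notochord <- trunk & abs(row - r0) <= g$notochord_halfwidth_px
  muscle <- trunk & !notochord
  if (g$n_somite_stripes > 0) {
    period <- g$trunk_length_px / g$n_somite_stripes
    # chevron phase: stripes slant away from the midline like somite boundaries
    phase <- (col - c0 + 0.6 * abs(row - r0)) %% period
    muscle <- muscle & phase < 0.5 * period
  }
  list(trunk = trunk, notochord = notochord, muscle = muscle)
}

#' Simulate a single embryo trunk image with known ground truth
#'
#' Renders a stylised embryo trunk (notochord band plus chevron muscle
#' stripes) on a dim background. The noiseless image is scaled so that the
#' mean intensity over the trunk mask equals exactly `baseline * fold`, which
#' makes programmed fold inductions exactly recoverable by the quantification
#' pipeline. Gaussian read noise (default) or Poisson shot noise can be
#' added; the result is clipped at zero.
#'
#' @param geometry An [image_geometry()].
#' @param fold Programmed fold induction over baseline (>= 0).
#' @param baseline Trunk mean intensity at fold 1.
#' @param noise_sd Standard deviation of additive Gaussian noise (ignored for
#'   `noise_model = "poisson"`).
#' @param seed Integer seed; identical inputs give bit-identical output.
#' @param background Background intensity outside the trunk.
#' @param notochord_muscle_ratio Relative brightness of notochord over muscle
#'   stripes (default 2).
#' @param noise_model `"gaussian"` (additive, default) or `"poisson"` (shot
#'   noise with the noiseless image as the rate).
#' @return A list with `image` (an [embryo_image()]) and `truth` (tissue
#'   masks, programmed fold, baseline, noise parameters, seed).
#' @examples
#' sim <- simulate_embryo_image(image_geometry(), fold = 3, noise_sd = 0)
#' mean(sim$image$pixels[sim$truth$masks$trunk])  # exactly 300
#' @export
simulate_embryo_image <- function(geometry = image_geometry(), fold = 1,
                                  baseline = 100, noise_sd = 0, seed = 1L,
                                  background = 5,
                                  notochord_muscle_ratio = 2,
                                  noise_model = c("gaussian", "poisson")) {
  noise_model <- match.arg(noise_model)
  validate_geometry(geometry)
  if (fold < 0) stop("fold must be >= 0", call. = FALSE)
  if (baseline <= 0) stop("baseline must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  masks <- render_tissue_masks(geometry)
  h <- geometry$height_px; w <- geometry$width_px
  # relative brightness field inside the trunk; scaled so the trunk mean is
  # exactly baseline * fold
  rel <- matrix(0, h, w)
  rel[masks$trunk] <- 0.6           # inter-stripe trunk tissue
  rel[masks$muscle] <- 1
  rel[masks$notochord] <- notochord_muscle_ratio
  mean_rel <- mean(rel[masks$trunk])
  noiseless <- matrix(background, h, w)
  noiseless[masks$trunk] <- rel[masks$trunk] * (baseline * fold / mean_rel)
  pix <- noiseless
  if (noise_model == "poisson") {
    set.seed(seed)
    pix <- matrix(stats::rpois(h * w, lambda = noiseless), h, w)
  } else if (noise_sd > 0) {
    set.seed(seed)
    pix <- noiseless + matrix(stats::rnorm(h * w, sd = noise_sd), h, w)
  }
  pix[pix < 0] <- 0
  list(
    image = embryo_image(pix, geometry$pixel_spacing_um),
    truth = list(masks = masks, programmed_fold = fold, baseline = baseline,
                 noise_sd = noise_sd, noise_model = noise_model, seed = seed,
                 noiseless_trunk_mean = baseline * fold)
  )
}

#' Simulate a full dose-series experiment with ground truth
#'
#' Generates `n_per_dose` embryo images at each concentration. The programmed
#' fold at each dose comes from a concentration-response model (dose 0, the
#' solvent control, is always fold 1); per-embryo biological variability is
#' added on the fold scale, pixel noise on the image scale. Everything is
#' deterministic under `seed`.
#'
#' @param doses Numeric vector of concentrations in uM; must contain 0 (the
#'   solvent control) or it is prepended with a warning.
#' @param cr_model A [gaussian_cr_model()] giving the programmed
#'   concentration-response.
#' @param n_per_dose Embryos per dose (>= 3).
#' @param baseline Trunk mean intensity of a control embryo.
#' @param fold_noise_sd Per-embryo Gaussian noise on the programmed fold.
#' @param pixel_noise_sd Additive Gaussian pixel noise.
#' @param geometry An [image_geometry()].
#' @param chemical Chemical label recorded in the metadata.
#' @param seed Integer seed.
#' @return A list with `images` (named list of [embryo_image()]),
#'   `metadata` (data.frame: embryo_id, chemical, concentration_uM, group),
#'   and `truth` (per-embryo programmed and realised folds, model, seed,
#'   per-embryo tissue masks are shared via `truth$masks`).
#' @export
simulate_dose_series <- function(doses, cr_model, n_per_dose = 10,
                                 baseline = 100, fold_noise_sd = 0,
                                 pixel_noise_sd = 0,
                                 geometry = image_geometry(),
                                 chemical = "chemA", seed = 1L) {
  if (length(doses) == 0) stop("empty dose list", call. = FALSE)
  if (any(doses < 0)) stop("doses must be non-negative", call. = FALSE)
  if (n_per_dose < 3) stop("n_per_dose must be >= 3", call. = FALSE)
  if (!0 %in% doses) {
    warning("no solvent control (dose 0) supplied; prepending one")
    doses <- c(0, doses)
  }
  doses <- sort(unique(doses))
  set.seed(seed)
  n_total <- length(doses) * n_per_dose
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  fold_jitter <- stats::rnorm(n_total, sd = fold_noise_sd)
  images <- vector("list", n_total)
  meta <- vector("list", n_total)
  truth_rows <- vector("list", n_total)
  idx <- 0L
  for (dose in doses) {
    programmed <- if (dose == 0) 1 else predict_cr(cr_model, dose)
    for (rep in seq_len(n_per_dose)) {
      idx <- idx + 1L
      realised <- max(0, programmed + fold_jitter[idx])
      sim <- simulate_embryo_image(geometry, fold = realised,
                                   baseline = baseline,
                                   noise_sd = pixel_noise_sd,
                                   seed = sub_seeds[idx])
      id <- sprintf("%s_d%g_r%02d", chemical, dose, rep)
      images[[idx]] <- sim$image
      names(images)[idx] <- id
      meta[[idx]] <- data.frame(
        embryo_id = id, chemical = chemical, concentration_uM = dose,
        group = if (dose == 0) "solvent_control" else "treated",
        stringsAsFactors = FALSE)
      truth_rows[[idx]] <- data.frame(
        embryo_id = id, concentration_uM = dose,
        programmed_fold = programmed, realised_fold = realised,
        stringsAsFactors = FALSE)
    }
  }
  masks <- render_tissue_masks(geometry)
  list(images = images,
       metadata = do.call(rbind, meta),
       truth = list(per_embryo = do.call(rbind, truth_rows),
                    cr_model = cr_model, baseline = baseline,
                    fold_noise_sd = fold_noise_sd,
                    pixel_noise_sd = pixel_noise_sd, seed = seed,
                    masks = masks))
}

#' Write a simulated dose series to disk
#'
#' Images are written as 16-bit grayscale TIFF, metadata as CSV (with an
#' `image_path` column), and the ground truth as JSON.
#'
#' @param bundle Result of [simulate_dose_series()].
#' @param dir Output directory (created if needed).
#' @param max_intensity Intensity mapped to the top of the 16-bit range.
#' @return Invisibly, the metadata data.frame with `image_path` filled in.
#' @export
write_dose_series <- function(bundle, dir, max_intensity = 1000) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- bundle$metadata
  meta$image_path <- file.path(dir, paste0(meta$embryo_id, ".tif"))
  for (i in seq_len(nrow(meta))) {
    write_embryo_image(bundle$images[[meta$embryo_id[i]]], meta$image_path[i],
                       max_intensity = max_intensity)
  }
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  truth <- bundle$truth
  truth$masks <- NULL  # boolean grids stay in memory, not in the JSON
  truth$cr_model <- unclass(truth$cr_model)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(meta)
}
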