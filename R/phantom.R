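# Seeded generator of mammogram-like phantom images with exact ground
# truth, so training, tracing and evaluation run with no external data.
#
# A phantom emulates the gross structure of an MLO-view mammogram: a
# near-black noisy background on the right, a breast region on the left
# bounded by a smooth open curve running from the top edge to the bottom
# edge, a darker textured transition band along that curve (the "boundary
# texture" the classifier learns), an interior whose intensity ramps up
# away from the boundary and carries correlated speckle, and optionally a
# bright pectoral-muscle wedge in the top-left corner and a bright label
# rectangle in the background. No radiometric realism is claimed.

#' Phantom generator configuration
#'
#' @param size (height, width) in pixels (default 512 x 512).
#' @param background_mean,background_std background intensity model
#'   (default 5 and 2; mammogram backgrounds are nearly black but noisy).
#' @param interior_peak intensity deep inside the breast (default 180).
#' @param interior_edge intensity of the interior right at the boundary
#'   band (default 40).
#' @param ramp_length distance in pixels over which the interior ramps
#'   from `interior_edge` to `interior_peak` (default 120).
#' @param boundary_band_width width of the textured transition band in
#'   pixels (default 15).
#' @param texture_correlation_length correlation length in pixels of the
#'   speckle fields (default 5).
#' @param interior_speckle,band_speckle multiplicative speckle amplitudes
#'   of the interior and of the band (defaults 0.10 and 0.35; the band
#'   carries visibly rougher texture).
#' @param band_noise_std additive Gaussian noise inside the band (default
#'   4; doubling it gives the "noisy boundary" condition).
#' @param noise_std global additive Gaussian noise (default 1).
#' @param curve_control_points number of spline control points of the
#'   boundary curve (default 5; more points give a wigglier curve).
#' @param pectoral add a bright pectoral wedge with its own ground-truth
#'   boundary (default `FALSE`).
#' @param label_artifact add a bright ~30 x 80 label rectangle in the
#'   background (default `FALSE`).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(size = c(512L, 512L), background_mean = 5,
                           background_std = 2, interior_peak = 180,
                           interior_edge = 40, ramp_length = 120,
                           boundary_band_width = 15,
                           texture_correlation_length = 5,
                           interior_speckle = 0.10, band_speckle = 0.35,
                           band_noise_std = 4, noise_std = 1,
                           curve_control_points = 5L, pectoral = FALSE,
                           label_artifact = FALSE, seed = 0L) {
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 64L)) {
    stop("`size` must be (height, width) with both >= 64", call. = FALSE)
  }
  if (boundary_band_width >= min(size) / 8) {
    stop("`boundary_band_width` must be < min(size) / 8", call. = FALSE)
  }
  structure(as.list(environment()), class = "phantom_config")
}

smooth_noise_field <- function(h, w, corr_len) {
  f <- EBImage::gblur(matrix(stats::rnorm(h * w), h, w), sigma = corr_len)
  f / stats::sd(f)
}

#' Generate one phantom image with ground truth
#'
#' @param config a [phantom_config()].
#' @return A list of class `phantom_sample` with `image` (integer matrix),
#'   `gt_boundary` (one point per row, ordered top to bottom),
#'   `gt_pectoral` (or `NULL`), and `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  h <- config$size[1L]; w <- config$size[2L]
  with_seed(config$seed, {
    # -- boundary curve: monotone in row, bulging rightward (MLO-like)
    n_ctrl <- max(3L, as.integer(config$curve_control_points))
    t_ctrl <- seq(0, 1, length.out = n_ctrl)
    # bulge kept gentle so ground-truth slopes stay within a tight angular
    # cluster, the regime the smoothness Gaussian is built for
    base <- w * (0.28 + 0.20 * 4 * t_ctrl * (1 - t_ctrl))
    jitter <- stats::runif(n_ctrl, -0.05, 0.05) * w
    ctrl_col <- pmin(pmax(base + jitter, 0.12 * w), 0.80 * w)
    cc <- stats::spline(x = t_ctrl * (h - 1), y = ctrl_col,
                        xout = 0:(h - 1), method = "natural")$y
    cc <- pmin(pmax(cc, 0.10 * w), 0.85 * w)
    gt <- boundary_points(0:(h - 1), round(cc))

    # -- per-pixel signed horizontal distance to the curve (+ = background)
    cols0 <- matrix(0:(w - 1), h, w, byrow = TRUE)
    D <- cols0 - cc # recycles cc down each column
    half <- config$boundary_band_width / 2
    img <- matrix(0, h, w)

    interior <- D < -half
    depth <- pmin(1, (-D - half) / config$ramp_length)
    base_int <- config$interior_edge +
      (config$interior_peak - config$interior_edge) * depth
    f_int <- smooth_noise_field(h, w, config$texture_correlation_length)
    img[interior] <- (base_int * (1 + config$interior_speckle * f_int))[interior]

    band <- abs(D) <= half
    bg_edge <- config$background_mean + 3
    base_band <- config$interior_edge +
      (bg_edge - config$interior_edge) *
        (D + half) / config$boundary_band_width
    f_band <- smooth_noise_field(h, w,
                                 max(2, config$texture_correlation_length / 2))
    band_val <- base_band * (1 + config$band_speckle * f_band) +
      stats::rnorm(h * w, 0, config$band_noise_std)
    img[band] <- band_val[band]

    background <- D > half
    img[background] <- config$background_mean +
      stats::rnorm(sum(background), 0, config$background_std)

    # -- optional pectoral wedge in the top-left corner
    gt_pect <- NULL
    if (isTRUE(config$pectoral)) {
      p_rows <- 0:round(0.40 * (h - 1))
      p_edge <- 0.22 * w * (1 - p_rows / max(p_rows))
      f_pect <- smooth_noise_field(h, w, config$texture_correlation_length)
      for (r in p_rows) {
        e <- round(p_edge[r + 1L])
        if (e >= 1L) {
          cols <- 1:e
          img[r + 1L, cols] <- 220 * (1 + 0.05 * f_pect[r + 1L, cols])
        }
      }
      keep <- round(p_edge) >= 1L
      gt_pect <- boundary_points(p_rows[keep], round(p_edge)[keep])
    }

    # -- optional bright label rectangle in the background
    if (isTRUE(config$label_artifact)) {
      lr <- round(0.10 * h) + seq_len(30L)
      lc <- round(0.97 * w) - rev(seq_len(80L))
      lc <- lc[lc > max(cc) + config$boundary_band_width]
      img[lr, lc] <- 240 + stats::rnorm(length(lr) * length(lc), 0, 2)
    }

    img <- img + stats::rnorm(h * w, 0, config$noise_std)
    img <- matrix(as.integer(pmin(255, pmax(0, round(img)))), h, w)
    structure(list(image = img, gt_boundary = gt, gt_pectoral = gt_pect,
                   config = config),
              class = "phantom_sample")
  })
}

derive_seeds <- function(seed, n, stream = 1L) {
  (as.numeric(seed) + 7919 * seq_len(n) + 104729 * stream) %% 2147483647
}

#' Generate a train/test phantom dataset on disk
#'
#' Writes `train/` and `test/` subdirectories of PGM images and matching
#' ground-truth boundary CSVs, plus a `manifest.json` recording every
#' parameter and per-sample seed (train and test use disjoint derived
#' seeds, so the sets never overlap).
#'
#' @param n_train,n_test number of phantoms per split (each >= 1).
#' @param config a [phantom_config()]; its `seed` field is ignored in
#'   favor of per-sample seeds derived from `seed`.
#' @param seed master seed.
#' @param dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return Invisibly, the manifest as a list.
#' @export
generate_dataset <- function(n_train, n_test, config = phantom_config(),
                             seed = 0L, dir, overwrite = FALSE) {
  stopifnot(n_train >= 1L, n_test >= 1L)
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !overwrite) {
    stop("output directory exists and is not empty: ", dir, call. = FALSE)
  }
  dir.create(file.path(dir, "train"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "test"), recursive = TRUE, showWarnings = FALSE)
  seeds <- list(train = derive_seeds(seed, n_train, stream = 1L),
                test = derive_seeds(seed, n_test, stream = 2L))
  files <- list()
  for (split in c("train", "test")) {
    for (i in seq_along(seeds[[split]])) {
      cfg <- config
      cfg$seed <- seeds[[split]][i]
      ph <- generate_phantom(cfg)
      img_path <- file.path(dir, split, sprintf("phantom_%02d.pgm", i))
      gt_path <- file.path(dir, split, sprintf("phantom_%02d_gt.csv", i))
      write_pgm(ph$image, img_path)
      write_boundary(ph$gt_boundary, gt_path)
      if (!is.null(ph$gt_pectoral)) {
        write_boundary(ph$gt_pectoral,
                       file.path(dir, split,
                                 sprintf("phantom_%02d_pectoral.csv", i)))
      }
      files[[length(files) + 1L]] <-
        list(split = split, image = basename(img_path),
             gt = basename(gt_path), seed = seeds[[split]][i])
    }
  }
  cfg_plain <- unclass(config)
  cfg_plain$seed <- NULL
  manifest <- list(package = "mammotrace", format_version = 1L,
                   master_seed = seed, n_train = n_train, n_test = n_test,
                   config = cfg_plain, files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Train texture and smoothness models from phantom samples
#'
#' Convenience wrapper over [collect_training_samples()],
#' [train_texture_model()], [collect_slope_vectors()] and
#' [fit_smoothness_model()]. Pass `which = "pectoral"` to train on the
#' pectoral ground truth instead of the breast boundary; the machinery is
#' identical.
#'
#' @param phantoms list of `phantom_sample` objects.
#' @param which `"breast"` (default) or `"pectoral"`.
#' @param window descriptor window (default 50).
#' @param n_negatives_per_image negatives per image (default 900).
#' @param gt_subsample take every `gt_subsample`-th ground-truth point as
#'   a positive-sample anchor (default 3; the anchor, its left and its
#'   right neighbor still all become positives). Ground-truth curves
#'   sampled at 1-px row spacing are heavily redundant at the 50-px window
#'   scale, so this thins the training set without losing coverage. The
#'   smoothness model always uses the full-resolution ground truth.
#' @param seed integer seed for sample collection and training.
#' @param ... further arguments to [train_texture_model()].
#' @return A list with elements `texture` and `smoothness`.
#' @export
train_boundary_model <- function(phantoms, which = c("breast", "pectoral"),
                                 window = 50L, n_negatives_per_image = 900L,
                                 gt_subsample = 3L, seed = 1L, ...) {
  which <- match.arg(which)
  images <- lapply(phantoms, `[[`, "image")
  gts <- lapply(phantoms, function(p) {
    if (which == "breast") p$gt_boundary else p$gt_pectoral
  })
  if (any(vapply(gts, is.null, logical(1L)))) {
    stop("requested ground truth missing from at least one phantom",
         call. = FALSE)
  }
  gts_thin <- lapply(gts, function(g) {
    g[seq(1L, nrow(g), by = max(1L, as.integer(gt_subsample))), ,
      drop = FALSE]
  })
  samples <- collect_training_samples(images, gts_thin, window = window,
                                      n_negatives_per_image =
                                        n_negatives_per_image,
                                      seed = seed)
  texture <- train_texture_model(samples, seed = seed + 1L, ...)
  slopes <- do.call(rbind, lapply(gts, collect_slope_vectors))
  smoothness <- fit_smoothness_model(slopes)
  list(texture = texture, smoothness = smoothness)
}
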