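# Sequential probabilistic boundary tracing.
#
# Starting from an initialization scan, the tracer repeatedly scores every
# candidate pixel within radius r of the current boundary head and appends
# the one maximizing the joint score
#   texture probability x smoothness density x Laplace prior,
# with factors enabled according to the ablation mode (T, TS, TSP). Only
# candidates classified "boundary" by the texture model are scored. The
# loop is fully deterministic: no randomness, row-major tie-breaking.

#' Tracing configuration
#'
#' @param window even descriptor window size; must match the texture
#'   model's training window (default 50).
#' @param radius candidate search radius r in pixels (default 20).
#' @param mode which joint-score factors to use: `"T"` texture only,
#'   `"TS"` texture x smoothness, `"TSP"` texture x smoothness x prior.
#' @param max_steps hard cap on the number of traced points (default 4000).
#' @param revisit_exclusion Chebyshev radius around already-accepted points
#'   from which new candidates are excluded; supplies the forward bias of
#'   the trace (default `floor(radius / 2)`).
#' @param prior a [prior_config()] for the Laplace factor.
#' @return A list of class `trace_config`.
#' @export
trace_config <- function(window = 50L, radius = 20L,
                         mode = c("TSP", "TS", "T"), max_steps = 4000L,
                         revisit_exclusion = floor(radius / 2),
                         prior = prior_config()) {
  mode <- match.arg(mode)
  radius <- as.integer(radius)
  if (radius < 2L) stop("`radius` must be >= 2", call. = FALSE)
  if (max_steps < 1L) stop("`max_steps` must be >= 1", call. = FALSE)
  structure(list(window = as.integer(window), radius = radius, mode = mode,
                 max_steps = as.integer(max_steps),
                 revisit_exclusion = as.integer(revisit_exclusion),
                 prior = prior),
            class = "trace_config")
}

# (row, col) offsets of the punctured Euclidean disk of given radius,
# row-major order; cached per radius.
.disk_cache <- new.env(parent = emptyenv())
disk_offsets <- function(radius) {
  key <- as.character(radius)
  if (!is.null(.disk_cache[[key]])) return(.disk_cache[[key]])
  g <- expand.grid(dc = -radius:radius, dr = -radius:radius)
  keep <- g$dr^2 + g$dc^2 <= radius^2 & !(g$dr == 0 & g$dc == 0)
  off <- cbind(row = g$dr[keep], col = g$dc[keep])
  off <- off[order(off[, 1L], off[, 2L]), , drop = FALSE]
  .disk_cache[[key]] <- off
  off
}

#' Candidate pixels around the current boundary head
#'
#' All pixels at Euclidean distance d with 0 < d <= radius from `current`
#' that lie inside the image and are not within the revisit-exclusion
#' Chebyshev radius of any already-accepted boundary point other than
#' `current`. Returned in row-major order.
#'
#' @param current length-2 (row, col) point.
#' @param previous matrix of already-accepted points excluding `current`
#'   (may have zero rows).
#' @param image_shape length-2 integer (height, width).
#' @param config a [trace_config()].
#' @return An m x 2 matrix of candidate (row, col) points.
#' @export
candidate_points <- function(current, previous, image_shape, config) {
  off <- disk_offsets(config$radius)
  pts <- cbind(row = off[, 1L] + current[1L], col = off[, 2L] + current[2L])
  keep <- pts[, 1L] >= 0L & pts[, 1L] < image_shape[1L] &
          pts[, 2L] >= 0L & pts[, 2L] < image_shape[2L]
  pts <- pts[keep, , drop = FALSE]
  if (!is.null(previous) && NROW(previous) > 0L && nrow(pts) > 0L) {
    prev <- rbind(previous)
    ex <- config$revisit_exclusion
    dr <- abs(outer(pts[, 1L], prev[, 1L], "-"))
    dc <- abs(outer(pts[, 2L], prev[, 2L], "-"))
    cheb <- pmax(dr, dc)
    pts <- pts[apply(cheb, 1L, min) > ex, , drop = FALSE]
  }
  pts
}

# Texture probabilities at the given pixels, memoized per trace in a
# matrix cache (the candidate disks of consecutive steps overlap heavily,
# and the ablation modes share every probability).
cached_texture_probability <- function(centers, model, lmap, window, cache) {
  idx <- centers[, 1L] + 1L + nrow(cache$p) * centers[, 2L]
  p <- cache$p[idx]
  miss <- which(is.na(p))
  if (length(miss) > 0L) {
    d <- patch_descriptor_matrix(lmap, centers[miss, , drop = FALSE], window)
    pm <- texture_probability(model, d)
    cache$p[idx[miss]] <- pm
    p[miss] <- pm
  }
  p
}

#' Create an empty per-pixel texture-probability cache
#'
#' @param h,w image height and width in pixels.
#' @return An environment holding the cache matrix; pass it to
#'   [trace_boundary()] to share SVM evaluations across runs on the same
#'   image.
#' @export
new_probability_cache <- function(h, w) {
  cache <- new.env(parent = emptyenv())
  cache$p <- matrix(NA_real_, h, w)
  cache
}

#' Find the starting point of the boundary
#'
#' Scans rows top to bottom; the first row containing any pixel classified
#' as boundary is evaluated in full and the pixel with maximum texture
#' probability in that row is returned (leftmost on ties). Under
#' marginalization over the unknown history the smoothness and prior
#' factors do not change this choice, so only the texture probability is
#' used. Returns `NULL` when no pixel in the image is classified boundary.
#'
#' @param image grayscale integer matrix.
#' @param model a trained `texture_model`.
#' @param window descriptor window (defaults to the model's).
#' @return A length-2 (row, col) point, or `NULL`.
#' @export
find_start_point <- function(image, model, window = model$window) {
  validate_image(image)
  lmap <- lbp_image(image, strict = model$strict)
  cache <- new_probability_cache(nrow(image), ncol(image))
  find_start_internal(image, model, lmap, window, cache)
}

find_start_internal <- function(image, model, lmap, window, cache) {
  h <- nrow(image); w <- ncol(image)
  for (r in 0:(h - 1L)) {
    centers <- cbind(row = rep(r, w), col = 0:(w - 1L))
    p <- cached_texture_probability(centers, model, lmap, window, cache)
    if (any(p >= 0.5)) {
      return(c(row = r, col = which.max(p) - 1L))
    }
  }
  NULL
}

score_joint <- function(texture_p, smooth_p, prior_p, mode, have_history) {
  joint <- texture_p
  if (mode %in% c("TS", "TSP") && have_history) joint <- joint * smooth_p
  if (mode == "TSP") joint <- joint * prior_p
  joint
}

#' Score a single candidate continuation point
#'
#' Assembles the joint score of a candidate already classified as boundary
#' texture: the texture probability, times the smoothness density when two
#' history points exist (modes TS/TSP), times the Laplace prior of the
#' texture probability (mode TSP). Steps without enough history use the
#' available factors only.
#'
#' @param candidate length-2 (row, col) candidate point.
#' @param p_k current boundary head.
#' @param p_k1 previous boundary point, or `NULL` at the second step.
#' @param texture_p texture probability of the candidate.
#' @param smoothness_model a `smoothness_model` (or `NULL` in mode T).
#' @param config a [trace_config()].
#' @return A list of class `candidate_score` with `point`, `texture_p`,
#'   `smooth_p`, `prior_p`, `joint`.
#' @export
score_candidate <- function(candidate, p_k, p_k1, texture_p,
                            smoothness_model, config) {
  have_hist <- !is.null(p_k1)
  smooth_p <- if (have_hist && config$mode %in% c("TS", "TSP")) {
    smoothness_probability(smoothness_model, candidate, p_k, p_k1)
  } else NA_real_
  prior_p <- if (config$mode == "TSP") {
    laplace_prior(texture_p, config$prior)
  } else NA_real_
  joint <- score_joint(texture_p,
                       if (is.na(smooth_p)) 1 else smooth_p,
                       if (is.na(prior_p)) 1 else prior_p,
                       config$mode, have_hist)
  structure(list(point = candidate, texture_p = texture_p,
                 smooth_p = smooth_p, prior_p = prior_p, joint = joint),
            class = "candidate_score")
}

#' Trace the breast boundary of an image
#'
#' Runs the initialization scan and then grows the boundary point by
#' point, at each step accepting the boundary-classified candidate with
#' maximum joint score (ties broken row-major). Tracing stops when no
#' candidate is classified boundary, when `max_steps` points have been
#' accepted, or when the trace reaches the image border away from its
#' starting region.
#'
#' @param image grayscale integer matrix.
#' @param texture_model a trained `texture_model`.
#' @param smoothness_model a `smoothness_model`; required for modes TS and
#'   TSP.
#' @param config a [trace_config()]; its window must match the texture
#'   model's training window.
#' @param cache optional texture-probability cache from
#'   [new_probability_cache()]; pass the same cache across runs on the
#'   same image to share per-pixel SVM evaluations (as [ablate_modes()]
#'   does).
#' @return An n x 2 (row, col) boundary matrix (possibly with zero rows),
#'   with attribute `termination` naming the stop reason.
#' @export
trace_boundary <- function(image, texture_model, smoothness_model = NULL,
                           config = trace_config(), cache = NULL) {
  validate_image(image)
  stopifnot(inherits(config, "trace_config"))
  if (!is.na(texture_model$window) &&
      config$window != texture_model$window) {
    stop("trace window (", config$window, ") does not match the window ",
         "the texture model was trained with (", texture_model$window, ")",
         call. = FALSE)
  }
  if (config$mode %in% c("TS", "TSP") && is.null(smoothness_model)) {
    stop("modes TS and TSP require a smoothness model", call. = FALSE)
  }
  h <- nrow(image); w <- ncol(image)
  lmap <- lbp_image(image, strict = texture_model$strict)
  if (is.null(cache)) cache <- new_probability_cache(h, w)

  start <- find_start_internal(image, texture_model, lmap, config$window,
                               cache)
  if (is.null(start)) {
    out <- boundary_points(integer(0), integer(0))
    attr(out, "termination") <- "no start point: no pixel classified boundary"
    return(out)
  }
  pts <- matrix(start, 1L, 2L, dimnames = list(NULL, c("row", "col")))
  termination <- "max_steps"
  on_border <- function(p) {
    p[1L] == 0L || p[1L] == h - 1L || p[2L] == 0L || p[2L] == w - 1L
  }
  while (nrow(pts) < config$max_steps) {
    k <- nrow(pts)
    current <- pts[k, ]
    previous <- pts[-k, , drop = FALSE]
    cand <- candidate_points(current, previous, c(h, w), config)
    if (nrow(cand) == 0L) { termination <- "no candidates"; break }
    tp <- cached_texture_probability(cand, texture_model, lmap,
                                     config$window, cache)
    keep <- tp >= 0.5
    if (!any(keep)) { termination <- "no boundary-classified candidate"; break }
    cand <- cand[keep, , drop = FALSE]
    tp <- tp[keep]
    joint <- tp
    if (config$mode %in% c("TS", "TSP") && k >= 2L) {
      p_k1 <- pts[k - 1L, ]
      theta_new <- atan2(cand[, 2L] - current[2L], cand[, 1L] - current[1L])
      theta_prev <- atan2(current[2L] - p_k1[2L], current[1L] - p_k1[1L])
      sp <- smoothness_density(smoothness_model,
                               cbind(theta_new, rep(theta_prev, length(theta_new))))
      joint <- joint * as.numeric(sp)
    }
    if (config$mode == "TSP") {
      joint <- joint * laplace_prior(tp, config$prior)
    }
    best <- which.max(joint) # candidates are row-major; first max wins ties
    accepted <- cand[best, ]
    pts <- rbind(pts, accepted)
    # border contact ends the trace, except in the starting region, which
    # legitimately touches the border where the curve enters the image
    if (on_border(accepted) &&
        max(abs(accepted - start)) > config$radius) {
      termination <- "border contact"
      break
    }
  }
  out <- boundary_points(pts[, 1L], pts[, 2L])
  attr(out, "termination") <- termination
  out
}

#' Trace one image under all three ablation modes
#'
#' Runs [trace_boundary()] in modes T, TS, and TSP with a shared
#' texture-probability cache (the texture factor is mode-independent, so
#' each pixel's SVM evaluation is paid once).
#'
#' @inheritParams trace_boundary
#' @param config a [trace_config()]; its `mode` is ignored.
#' @return A named list of boundaries `T`, `TS`, `TSP`.
#' @export
ablate_modes <- function(image, texture_model, smoothness_model,
                         config = trace_config()) {
  cache <- new_probability_cache(nrow(image), ncol(image))
  out <- lapply(c("T", "TS", "TSP"), function(m) {
    cfg <- config
    cfg$mode <- m
    trace_boundary(image, texture_model, smoothness_model, cfg, cache = cache)
  })
  names(out) <- c("T", "TS", "TSP")
  out
}

#' Ablation study over a test set
#'
#' Traces every image in all three modes and compares each result to its
#' ground truth, mirroring a per-image results table with column means and
#' standard deviations.
#'
#' @param images list of grayscale integer matrices.
#' @param gt_list list of matching ground-truth boundaries.
#' @inheritParams ablate_modes
#' @return A data.frame with one row per (image, mode) holding `acc_mean`
#'   and `curve_diff`, plus attributes `mean` and `sd`: mode-by-metric
#'   summary matrices.
#' @export
run_ablation <- function(images, gt_list, texture_model, smoothness_model,
                         config = trace_config()) {
  stopifnot(length(images) == length(gt_list))
  rows <- list()
  for (i in seq_along(images)) {
    traced <- ablate_modes(images[[i]], texture_model, smoothness_model,
                           config)
    for (m in names(traced)) {
      b <- traced[[m]]
      cmp <- if (nrow(b) >= 3L) compare_boundaries(b, gt_list[[i]]) else
        list(acc_mean = NA_real_, curve_diff = NA_real_)
      rows[[length(rows) + 1L]] <-
        data.frame(image = i, mode = m, n_points = nrow(b),
                   acc_mean = cmp$acc_mean, curve_diff = cmp$curve_diff)
    }
  }
  out <- do.call(rbind, rows)
  agg <- function(f) {
    vapply(c("T", "TS", "TSP"), function(m) {
      c(acc_mean = f(out$acc_mean[out$mode == m]),
        curve_diff = f(out$curve_diff[out$mode == m]))
    }, numeric(2L))
  }
  attr(out, "mean") <- agg(function(v) mean(v, na.rm = TRUE))
  attr(out, "sd") <- agg(function(v) stats::sd(v[!is.na(v)]))
  out
}
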