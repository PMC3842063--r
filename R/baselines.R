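# Comparison baselines: a greedy (window-search) active contour and a
# threshold + morphology boundary extractor.
#
# Snake energy: E = sum_i E_external(v_i) + E_internal(v_i) with
#   E_external(v) = -|grad(Gaussian(sigma) * I)(v)| * alpha
#   E_internal(v) = beta * ||v_i - v_{i-1}||^2
#                 + gamma * ||v_{i+1} - 2 v_i + v_{i-1}||^2.
# Note the term attached to beta is the first difference and the term
# attached to gamma the second difference; the conventional snake
# literature names these continuity and curvature respectively, i.e. the
# labels here are swapped relative to that convention, but the weights
# stay attached to the formulas as written above.

#' Snake configuration
#'
#' @param alpha,beta,gamma non-negative energy weights.
#' @param sigma Gaussian smoothing width of the external energy (pixels).
#' @param search_window odd side length of the per-vertex search window.
#' @param max_iterations iteration cap.
#' @return A list of class `snake_config`.
#' @export
snake_config <- function(alpha = 1, beta = 0, gamma = 0, sigma = 3,
                         search_window = 5L, max_iterations = 100L) {
  search_window <- as.integer(search_window)
  if (search_window < 3L || search_window %% 2L == 0L) {
    stop("`search_window` must be an odd integer >= 3", call. = FALSE)
  }
  if (any(c(alpha, beta, gamma) < 0)) {
    stop("energy weights must be non-negative", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma, sigma = sigma,
                 search_window = search_window,
                 max_iterations = as.integer(max_iterations)),
            class = "snake_config")
}

#' External (image) energy field
#'
#' Negative gradient magnitude of the Gaussian-smoothed image (central
#' differences); non-positive everywhere, with minima along strong edges.
#' The `alpha` weight is applied at evaluation time, not here.
#'
#' @param image grayscale integer matrix.
#' @param sigma Gaussian smoothing width (> 0).
#' @return A numeric matrix of the same shape, `<= 0` everywhere.
#' @export
external_energy <- function(image, sigma = 3) {
  validate_image(image)
  stopifnot(sigma > 0)
  s <- EBImage::gblur(image * 1.0, sigma = sigma)
  sp <- replicate_pad(s, 1L)
  h <- nrow(s); w <- ncol(s)
  gr <- (sp[3:(h + 2L), 2:(w + 1L)] - sp[1:h, 2:(w + 1L)]) / 2
  gc <- (sp[2:(h + 1L), 3:(w + 2L)] - sp[2:(h + 1L), 1:w]) / 2
  -sqrt(gr^2 + gc^2)
}

snake_vertex_energy <- function(v, v_prev, v_next, energy_field, config) {
  e <- config$alpha * energy_field[v[1L] + 1L, v[2L] + 1L]
  if (!is.null(v_prev)) {
    e <- e + config$beta * sum((v - v_prev)^2)
    if (!is.null(v_next)) {
      e <- e + config$gamma * sum((v_next - 2 * v + v_prev)^2)
    }
  }
  e
}

#' One greedy snake iteration
#'
#' Each vertex moves, in index order, to the position inside its search
#' window minimizing its own energy terms; neighbor positions are taken
#' from the start of the iteration, so the update is deterministic and
#' order-independent. Terms needing missing neighbors (at the contour
#' ends) are dropped. A vertex moves only if it strictly lowers its
#' energy.
#'
#' @param contour n x 2 (row, col) vertex matrix (n >= 3).
#' @param energy_field external energy from [external_energy()].
#' @param config a [snake_config()].
#' @return A list with `contour` (updated matrix) and `moved` (number of
#'   vertices that moved).
#' @export
greedy_snake_step <- function(contour, energy_field, config) {
  stopifnot(is.matrix(contour), ncol(contour) == 2L, nrow(contour) >= 3L)
  h <- nrow(energy_field); w <- ncol(energy_field)
  half <- config$search_window %/% 2L
  old <- contour
  n <- nrow(contour)
  moved <- 0L
  for (i in seq_len(n)) {
    v_prev <- if (i > 1L) old[i - 1L, ] else NULL
    v_next <- if (i < n) old[i + 1L, ] else NULL
    best_v <- contour[i, ]
    best_e <- snake_vertex_energy(best_v, v_prev, v_next, energy_field,
                                  config)
    for (dr in -half:half) {
      for (dc in -half:half) {
        v <- old[i, ] + c(dr, dc)
        if (v[1L] < 0L || v[1L] >= h || v[2L] < 0L || v[2L] >= w) next
        e <- snake_vertex_energy(v, v_prev, v_next, energy_field, config)
        if (e < best_e - 1e-12) {
          best_e <- e
          best_v <- v
        }
      }
    }
    if (any(best_v != old[i, ])) moved <- moved + 1L
    contour[i, ] <- best_v
  }
  list(contour = contour, moved = moved)
}

snake_total_energy <- function(contour, energy_field, config) {
  n <- nrow(contour)
  sum(vapply(seq_len(n), function(i) {
    snake_vertex_energy(contour[i, ],
                        if (i > 1L) contour[i - 1L, ] else NULL,
                        if (i < n) contour[i + 1L, ] else NULL,
                        energy_field, config)
  }, numeric(1L)))
}

#' Run the greedy snake to convergence
#'
#' @param image grayscale integer matrix.
#' @param init initial contour, n x 2 (row, col) matrix.
#' @param config a [snake_config()].
#' @return The refined contour, with attributes `iterations` and
#'   `energy_trace` (total energy after each iteration, starting with the
#'   initial contour's energy).
#' @export
greedy_snake <- function(image, init, config = snake_config()) {
  validate_boundary(init, "init")
  ef <- external_energy(image, config$sigma)
  contour <- init
  energies <- snake_total_energy(contour, ef, config)
  it <- 0L
  while (it < config$max_iterations) {
    it <- it + 1L
    res <- greedy_snake_step(contour, ef, config)
    contour <- res$contour
    energies <- c(energies, snake_total_energy(contour, ef, config))
    if (res$moved == 0L) break
  }
  attr(contour, "iterations") <- it
  attr(contour, "energy_trace") <- energies
  contour
}

#' Threshold + morphology boundary extraction
#'
#' Otsu threshold, largest connected foreground component, 3 x 3
#' morphological closing, then the component's outer edge traced as the
#' per-row extremal foreground pixel on the background side (the
#' right-hand interface under this package's left-breast convention).
#'
#' @param image grayscale integer matrix.
#' @return An n x 2 (row, col) boundary, top to bottom; zero rows when no
#'   foreground is found.
#' @export
threshold_boundary <- function(image) {
  validate_image(image)
  x <- image / 255
  thr <- EBImage::otsu(EBImage::Image(x, colormode = "Grayscale"))
  mask <- x > thr
  if (!any(mask)) return(boundary_points(integer(0), integer(0)))
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1, colormode = "Grayscale"))
  lab <- EBImage::imageData(lab)
  counts <- tabulate(lab[lab > 0])
  mask <- lab == which.max(counts)
  mask <- EBImage::imageData(EBImage::closing(
    EBImage::Image(mask * 1, colormode = "Grayscale"),
    EBImage::makeBrush(3L, "box"))) > 0.5
  rows <- which(apply(mask, 1L, any))
  cols <- vapply(rows, function(r) max(which(mask[r, ])), integer(1L))
  boundary_points(rows - 1L, cols - 1L)
}
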