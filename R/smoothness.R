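# Bivariate-Gaussian model of consecutive boundary-segment slopes.
#
# For a boundary P^1..P^n (points as (row, col); x = col, y = row) the
# slope vector at index k is
#   ( atan2(x_k - x_{k-1}, y_k - y_{k-1}),
#     atan2(x_{k-1} - x_{k-2}, y_{k-1} - y_{k-2}) )
# with the x-difference as the first atan2 argument — an unusual but
# internally consistent convention kept identical at training and tracing
# time. At trace time the candidate point plays the role of the newest
# point, so the density scores how well a candidate continues the local
# direction of the curve.

wrap_angle <- function(a) {
  # wrap into (-pi, pi]
  w <- a - 2 * pi * floor((a + pi) / (2 * pi))
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

#' Slope vectors along a boundary
#'
#' @param boundary n x 2 (row, col) matrix with n >= 3 and distinct
#'   consecutive points.
#' @return An (n - 2) x 2 matrix with columns `theta_new`, `theta_prev`
#'   (radians in (-pi, pi\]).
#' @export
collect_slope_vectors <- function(boundary) {
  validate_boundary(boundary)
  n <- nrow(boundary)
  if (n < 3L) stop("need at least 3 boundary points", call. = FALSE)
  dx <- diff(boundary[, 2L]) # x = col
  dy <- diff(boundary[, 1L]) # y = row
  same <- which(dx == 0 & dy == 0)
  if (length(same) > 0L) {
    stop("repeated consecutive boundary point at index ", same[1L] + 1L,
         call. = FALSE)
  }
  theta <- atan2(dx, dy)
  cbind(theta_new = theta[-1L], theta_prev = theta[-(n - 1L)])
}

#' Fit the bivariate Gaussian smoothness model
#'
#' Maximum-likelihood mean and covariance (divide-by-N) of the slope
#' vectors, with `epsilon` added to the covariance diagonal so that
#' near-collinear training boundaries still give a positive-definite model.
#'
#' @param slopes m x 2 matrix of slope vectors (m >= 3), e.g. rbind-ed
#'   output of [collect_slope_vectors()] over all training boundaries.
#' @param epsilon diagonal regularization (default 1e-6).
#' @return A list of class `smoothness_model` with `mean`, `covariance`,
#'   `epsilon`.
#' @export
fit_smoothness_model <- function(slopes, epsilon = 1e-6) {
  stopifnot(is.matrix(slopes), ncol(slopes) == 2L)
  if (nrow(slopes) < 3L) {
    stop("need at least 3 slope vectors to fit the model", call. = FALSE)
  }
  mu <- colMeans(slopes)
  xc <- sweep(slopes, 2L, mu)
  sigma <- crossprod(xc) / nrow(slopes) + diag(epsilon, 2L)
  structure(list(mean = unname(mu), covariance = unname(sigma),
                 epsilon = epsilon),
            class = "smoothness_model")
}

# Density of the model at given slope vectors (rows). Residuals are
# wrapped componentwise into (-pi, pi] before the quadratic form: slopes
# are circular, and wrapping prevents spuriously low densities near +-pi.
smoothness_density <- function(model, slopes, wrap = TRUE) {
  if (!is.matrix(slopes)) slopes <- rbind(slopes)
  r <- sweep(slopes, 2L, model$mean)
  if (wrap) r <- wrap_angle(r)
  s <- model$covariance
  det_s <- s[1L, 1L] * s[2L, 2L] - s[1L, 2L] * s[2L, 1L]
  inv <- matrix(c(s[2L, 2L], -s[1L, 2L], -s[2L, 1L], s[1L, 1L]), 2L) / det_s
  q <- rowSums((r %*% inv) * r)
  exp(-q / 2) / (2 * pi * sqrt(det_s))
}

#' Smoothness density of a candidate continuation point
#'
#' Evaluates the fitted bivariate Gaussian at the slope vector formed with
#' `candidate` as the newest point after `p_k` and `p_k1`:
#' `x = (atan2(x_c - x_k, y_c - y_k), atan2(x_k - x_k1, y_k - y_k1))`.
#' The standard bivariate normalizer `1 / (2 * pi * sqrt(det(Sigma)))` is
#' used; the shared constant does not affect which candidate wins.
#'
#' @param model a `smoothness_model`.
#' @param candidate,p_k,p_k1 length-2 (row, col) points; `candidate` must
#'   differ from `p_k`, and `p_k` from `p_k1`.
#' @return A positive density value.
#' @export
smoothness_probability <- function(model, candidate, p_k, p_k1) {
  stopifnot(inherits(model, "smoothness_model"))
  if (all(candidate == p_k) || all(p_k == p_k1)) {
    stop("coincident points: slope vector is undefined", call. = FALSE)
  }
  theta_new <- atan2(candidate[2L] - p_k[2L], candidate[1L] - p_k[1L])
  theta_prev <- atan2(p_k[2L] - p_k1[2L], p_k[1L] - p_k1[1L])
  as.numeric(smoothness_density(model, c(theta_new, theta_prev)))
}
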