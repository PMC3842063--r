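# Local binary pattern codes and 4-subregion window descriptors.
#
# The LBP code of a pixel with intensity z0 and 8-neighborhood z1..z8 is
#   sum_{i=1..8} 2^(i-1) * delta(z_i - z0)
# where delta(u) = 1 iff u >= 1 (neighbor strictly brighter than the
# center). Neighbors are ordered clockwise starting at the top-left:
#   z1 = (-1,-1), z2 = (-1,0), z3 = (-1,+1), z4 = (0,+1),
#   z5 = (+1,+1), z6 = (+1,0), z7 = (+1,-1), z8 = (0,-1)
# as (row, col) offsets. Any fixed order would do as long as training and
# tracing agree; this one is the package-wide convention.

lbp_offsets <- matrix(c(-1L, -1L,
                        -1L,  0L,
                        -1L,  1L,
                         0L,  1L,
                         1L,  1L,
                         1L,  0L,
                         1L, -1L,
                         0L, -1L), ncol = 2L, byrow = TRUE)

#' LBP code of a single 3x3 neighborhood
#'
#' @param patch a 3x3 numeric matrix of intensities in \[0, 255\]; the
#'   center pixel is `patch[2, 2]`.
#' @param strict use the strictly-greater threshold `delta(u) = 1` iff
#'   `u >= 1` (default). With `strict = FALSE` the common LBP convention
#'   `u >= 0` (neighbor greater *or equal*) is used instead.
#' @return An integer in \[0, 255\].
#' @export
lbp_value <- function(patch, strict = TRUE) {
  if (!is.matrix(patch) || any(dim(patch) != c(3L, 3L))) {
    stop("`patch` must be a 3x3 matrix", call. = FALSE)
  }
  validate_image(patch, "patch")
  z0 <- patch[2L, 2L]
  code <- 0L
  for (i in 1:8) {
    zi <- patch[2L + lbp_offsets[i, 1L], 2L + lbp_offsets[i, 2L]]
    d <- zi - z0
    hit <- if (strict) d >= 1 else d >= 0
    if (hit) code <- code + bitwShiftL(1L, i - 1L)
  }
  code
}

replicate_pad <- function(m, k) {
  ri <- pmin(pmax(seq_len(nrow(m) + 2L * k) - k, 1L), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m) + 2L * k) - k, 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

#' Per-pixel LBP code map of an image
#'
#' The image is replicate-padded by one pixel so border pixels get codes
#' too (their out-of-image neighbors are copies of the border, which never
#' satisfy the strictly-greater test against themselves).
#'
#' @param image integer matrix with intensities in \[0, 255\].
#' @inheritParams lbp_value
#' @return An integer matrix of LBP codes in \[0, 255\], same shape as
#'   `image`.
#' @export
lbp_image <- function(image, strict = TRUE) {
  validate_image(image)
  p <- replicate_pad(image, 1L)
  h <- nrow(image); w <- ncol(image)
  ctr <- p[2:(h + 1L), 2:(w + 1L), drop = FALSE]
  codes <- matrix(0L, h, w)
  for (i in 1:8) {
    dr <- lbp_offsets[i, 1L]; dc <- lbp_offsets[i, 2L]
    nb <- p[(2L + dr):(h + 1L + dr), (2L + dc):(w + 1L + dc), drop = FALSE]
    d <- nb - ctr
    hit <- if (strict) d >= 1 else d >= 0
    codes <- codes + bitwShiftL(1L, i - 1L) * hit
  }
  storage.mode(codes) <- "integer"
  codes
}

#' 4-subregion LBP histogram descriptor of a window
#'
#' The even `window` x `window` crop centered on a pixel (the center sits at
#' offset (window/2, window/2) from the crop's top-left corner) is split
#' into four equal quadrants — top-left, top-right, bottom-left,
#' bottom-right — and a 256-bin histogram of LBP codes is taken per
#' quadrant. Concatenating the four histograms in that order gives a
#' 1024-long raw descriptor. Crops extending past the image are clamped by
#' replicating edge codes, so a descriptor is defined for every pixel.
#'
#' @param lbp_map integer matrix of LBP codes (from [lbp_image()]).
#' @param center length-2 integer vector, 0-based (row, col) of the window
#'   center.
#' @param window even window size >= 2 (default 50).
#' @return Numeric vector of length `4 * 256 = 1024` of raw bin counts;
#'   each 256-bin block sums to `(window/2)^2`.
#' @export
patch_descriptor <- function(lbp_map, center, window = 50L) {
  d <- patch_descriptor_matrix(lbp_map, rbind(center), window)
  d[1L, ]
}

#' Batch form of [patch_descriptor()]
#'
#' @inheritParams patch_descriptor
#' @param centers n x 2 matrix of 0-based (row, col) window centers.
#' @return An n x 1024 numeric matrix, one raw descriptor per row.
#' @export
patch_descriptor_matrix <- function(lbp_map, centers, window = 50L) {
  stopifnot(is.matrix(lbp_map), is.matrix(centers), ncol(centers) == 2L)
  window <- as.integer(window)
  if (window < 2L || window %% 2L != 0L) {
    stop("`window` must be an even integer >= 2", call. = FALSE)
  }
  h <- nrow(lbp_map); w <- ncol(lbp_map)
  if (any(centers[, 1L] < 0L) || any(centers[, 1L] >= h) ||
      any(centers[, 2L] < 0L) || any(centers[, 2L] >= w)) {
    stop("window center outside the image", call. = FALSE)
  }
  half <- window %/% 2L
  padded <- replicate_pad(lbp_map, half)
  storage.mode(padded) <- "integer"
  out <- .desc_matrix_cpp(padded,
                          as.integer(centers[, 1L]),
                          as.integer(centers[, 2L]), window)
  t(out) * 1.0
}

#' Fit a PCA basis on raw descriptors
#'
#' Eigen-decomposition of the sample covariance of the mean-centered
#' descriptors. The number of retained components is the smallest index at
#' which the cumulative eigenvalue fraction exceeds `threshold` (0.99 by
#' default).
#'
#' @param descriptors n x d numeric matrix, one raw descriptor per row.
#' @param threshold cumulative explained-variance cutoff in (0, 1).
#' @return A list of class `pca_basis` with elements `mean`, `components`
#'   (d x d orthonormal columns, eigenvalue-descending), `eigenvalues`, and
#'   `n_retained`.
#' @export
fit_pca <- function(descriptors, threshold = 0.99) {
  stopifnot(is.matrix(descriptors))
  if (nrow(descriptors) < 2L) {
    stop("need at least 2 descriptors to fit a PCA basis", call. = FALSE)
  }
  mu <- colMeans(descriptors)
  xc <- sweep(descriptors, 2L, mu)
  cv <- crossprod(xc) / (nrow(descriptors) - 1L)
  if (sum(diag(cv)) <= 0) {
    stop("descriptors have zero total variance; PCA is undefined",
         call. = FALSE)
  }
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  frac <- cumsum(ev) / sum(ev)
  n_ret <- which(frac > threshold)[1L]
  structure(list(mean = mu, components = eg$vectors, eigenvalues = ev,
                 n_retained = as.integer(n_ret)),
            class = "pca_basis")
}

#' Project raw descriptors onto a fitted PCA basis
#'
#' @param basis a `pca_basis` from [fit_pca()].
#' @param descriptors a single raw descriptor (vector) or an n x d matrix.
#' @return Mean-centered scores on the first `n_retained` components: a
#'   vector, or an n x n_retained matrix for matrix input.
#' @export
pca_project <- function(basis, descriptors) {
  stopifnot(inherits(basis, "pca_basis"))
  vec_in <- !is.matrix(descriptors)
  if (vec_in) descriptors <- rbind(descriptors)
  if (ncol(descriptors) != length(basis$mean)) {
    stop("descriptor dimension (", ncol(descriptors),
         ") does not match the PCA basis (", length(basis$mean), ")",
         call. = FALSE)
  }
  sc <- sweep(descriptors, 2L, basis$mean) %*%
    basis$components[, seq_len(basis$n_retained), drop = FALSE]
  if (vec_in) sc[1L, ] else sc
}
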