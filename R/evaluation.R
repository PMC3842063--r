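# Boundary comparison metrics: mean perpendicular deviation from the
# ground-truth polyline (acc_mean) and a first+second finite-difference
# curve-smoothness measure.

#' Perpendicular distance from a point to the line through two points
#'
#' Uses the slope-free form `|dx (y_e - y1) - dy (x_e - x1)| /
#' sqrt(dx^2 + dy^2)`, which is defined for vertical lines too.
#'
#' @param p_e,g1,g2 length-2 (row, col) points; `g1` must differ from `g2`.
#' @return A non-negative distance in pixels.
#' @export
point_line_distance <- function(p_e, g1, g2) {
  if (all(g1 == g2)) {
    stop("the two ground-truth points coincide; no line is defined",
         call. = FALSE)
  }
  # x = col, y = row; the formula is symmetric in the convention anyway
  dxy <- g2 - g1
  abs(dxy[1L] * (p_e[2L] - g1[2L]) - dxy[2L] * (p_e[1L] - g1[1L])) /
    sqrt(sum(dxy^2))
}

#' Mean perpendicular deviation of an extracted boundary from ground truth
#'
#' For every extracted point the two nearest (Euclidean) distinct
#' ground-truth points are found — ties resolved in favor of a pair
#' adjacent in ground-truth order, whose connecting line is the intended
#' local segment — and the perpendicular distance to the line through them
#' is taken. The mean over all extracted points is returned. The measure
#' is not symmetric in its arguments.
#'
#' @param extracted non-empty n x 2 (row, col) boundary.
#' @param gt ground-truth boundary with at least 2 distinct points.
#' @return Mean deviation in pixels (>= 0).
#' @export
acc_mean <- function(extracted, gt) {
  validate_boundary(extracted, "extracted")
  validate_boundary(gt, "gt")
  if (nrow(extracted) == 0L) stop("`extracted` is empty", call. = FALSE)
  if (nrow(gt) < 2L || nrow(unique(gt)) < 2L) {
    stop("`gt` must contain at least two distinct points", call. = FALSE)
  }
  d_each <- vapply(seq_len(nrow(extracted)), function(j) {
    p <- extracted[j, ]
    d2 <- (gt[, 1L] - p[1L])^2 + (gt[, 2L] - p[2L])^2
    k <- which.min(d2)
    # second nearest among points distinct in coordinates from gt[k, ]
    distinct <- !(gt[, 1L] == gt[k, 1L] & gt[, 2L] == gt[k, 2L])
    cand <- which(distinct)
    d2c <- d2[cand]
    best <- d2c == min(d2c)
    tied <- cand[best]
    adj <- tied[abs(tied - k) == 1L]
    k2 <- if (length(adj) > 0L) adj[1L] else tied[1L]
    point_line_distance(p, gt[k, ], gt[k2, ])
  }, numeric(1L))
  mean(d_each)
}

#' Curve-smoothness measure of a boundary
#'
#' Sum over the interior points j = 2..m-1 of the squared first-difference
#' norm plus the squared second-difference norm; the endpoints contribute
#' nothing. Low values mean a smooth, unstretched curve; jittery
#' extractions score high. Invariant to translation and rotation.
#'
#' @param boundary m x 2 (row, col) matrix with m >= 3.
#' @return A non-negative scalar.
#' @export
curve_measure <- function(boundary) {
  validate_boundary(boundary)
  curve_measure_numeric(boundary)
}

# core on arbitrary (possibly non-integer) coordinates
curve_measure_numeric <- function(boundary) {
  m <- nrow(boundary)
  if (m < 3L) stop("need at least 3 points for the curve measure",
                   call. = FALSE)
  d1 <- diff(boundary)             # rows 1..m-1: p_j - p_{j-1} at j = 2..m
  d2 <- diff(boundary, differences = 2L) # rows 1..m-2: at j = 2..m-1
  j <- 2:(m - 1L)
  sum(rowSums(d1[j - 1L, , drop = FALSE]^2)) +
    sum(rowSums(d2[j - 1L, , drop = FALSE]^2))
}

#' Compare an extracted boundary against ground truth
#'
#' @param extracted,gt boundaries as n x 2 (row, col) matrices.
#' @return A list of class `boundary_comparison` with `acc_mean`,
#'   `curve_extracted`, `curve_gt`, and `curve_diff` (the absolute
#'   difference of the two curve measures).
#' @export
compare_boundaries <- function(extracted, gt) {
  ce <- curve_measure(extracted)
  cg <- curve_measure(gt)
  structure(list(acc_mean = acc_mean(extracted, gt),
                 curve_extracted = ce, curve_gt = cg,
                 curve_diff = abs(ce - cg)),
            class = "boundary_comparison")
}

#' Aggregate comparisons over pairs of boundaries
#'
#' @param extracted_list,gt_list lists of boundaries, pairwise matched.
#' @return A data.frame with one row per pair plus attributes `mean` and
#'   `sd` (named vectors over the four comparison quantities).
#' @export
evaluate_batch <- function(extracted_list, gt_list) {
  stopifnot(length(extracted_list) == length(gt_list))
  rows <- lapply(seq_along(extracted_list), function(i) {
    cmp <- compare_boundaries(extracted_list[[i]], gt_list[[i]])
    data.frame(pair = i, acc_mean = cmp$acc_mean,
               curve_extracted = cmp$curve_extracted,
               curve_gt = cmp$curve_gt, curve_diff = cmp$curve_diff)
  })
  out <- do.call(rbind, rows)
  num <- c("acc_mean", "curve_extracted", "curve_gt", "curve_diff")
  attr(out, "mean") <- vapply(out[num], mean, numeric(1L))
  attr(out, "sd") <- vapply(out[num], stats::sd, numeric(1L))
  out
}
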