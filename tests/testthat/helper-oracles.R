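# Independent brute-force oracles used to pin the fast implementations.

# bit-by-bit LBP oracle over the 8 comparisons
oracle_lbp <- function(patch, strict = TRUE) {
  off <- matrix(c(-1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1, 0, -1),
                ncol = 2, byrow = TRUE)
  z0 <- patch[2, 2]
  s <- 0L
  for (i in 1:8) {
    d <- patch[2 + off[i, 1], 2 + off[i, 2]] - z0
    hit <- if (strict) d >= 1 else d >= 0
    if (hit) s <- s + bitwShiftL(1L, i - 1L)
  }
  s
}

# naive crop-split-count descriptor oracle (clamped indices = edge
# replication)
oracle_descriptor <- function(lmap, center, w) {
  half <- w / 2
  ri <- pmin(pmax((center[1] - half):(center[1] + half - 1) + 1, 1), nrow(lmap))
  ci <- pmin(pmax((center[2] - half):(center[2] + half - 1) + 1, 1), ncol(lmap))
  crop <- lmap[ri, ci]
  qs <- list(crop[1:half, 1:half], crop[1:half, half + 1:half],
             crop[half + 1:half, 1:half], crop[half + 1:half, half + 1:half])
  unlist(lapply(qs, function(q) tabulate(as.vector(q) + 1L, 256L)))
}

# all-pairs nearest-two-points + perpendicular-distance oracle for acc_mean
oracle_acc_mean <- function(extracted, gt) {
  mean(vapply(seq_len(nrow(extracted)), function(j) {
    p <- extracted[j, ]
    d2 <- (gt[, 1] - p[1])^2 + (gt[, 2] - p[2])^2
    k <- which.min(d2)
    distinct <- !(gt[, 1] == gt[k, 1] & gt[, 2] == gt[k, 2])
    cand <- which(distinct)
    tied <- cand[d2[cand] == min(d2[cand])]
    adj <- tied[abs(tied - k) == 1]
    k2 <- if (length(adj) > 0) adj[1] else tied[1]
    g1 <- gt[k, ]; g2 <- gt[k2, ]
    v <- g2 - g1
    abs(v[1] * (p[2] - g1[2]) - v[2] * (p[1] - g1[1])) / sqrt(sum(v^2))
  }, numeric(1)))
}

# brute-force punctured-disk lattice enumeration
oracle_disk_points <- function(center, radius, shape) {
  pts <- NULL
  for (r in 0:(shape[1] - 1)) {
    for (c in 0:(shape[2] - 1)) {
      d2 <- (r - center[1])^2 + (c - center[2])^2
      if (d2 > 0 && d2 <= radius^2) pts <- rbind(pts, c(r, c))
    }
  }
  pts
}

# 2-D synthetic two-blob sample generator used by the texture-model tests:
# well-separated Gaussian blobs standing in for projected descriptors
two_blob_samples <- function(n_per_class = 200, sep = 3, sd = 0.1,
                             seed = 1, dim = 2) {
  set.seed(seed)
  mu_pos <- c(sep / 2, rep(0, dim - 1))
  mu_neg <- c(-sep / 2, rep(0, dim - 1))
  x <- rbind(
    matrix(rnorm(n_per_class * dim, sd = sd), ncol = dim,
           byrow = TRUE) + matrix(mu_pos, n_per_class, dim, byrow = TRUE),
    matrix(rnorm(n_per_class * dim, sd = sd), ncol = dim,
           byrow = TRUE) + matrix(mu_neg, n_per_class, dim, byrow = TRUE))
  list(descriptors = x,
       label = factor(rep(c("boundary", "nonboundary"), each = n_per_class),
                      levels = c("boundary", "nonboundary")),
       mu_pos = mu_pos, mu_neg = mu_neg)
}
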