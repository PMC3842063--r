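test_that("lbp_value matches the bit-by-bit oracle and its closed cases", {
  expect_identical(lbp_value(matrix(100, 3, 3)), 0L)
  p <- matrix(255, 3, 3); p[2, 2] <- 0
  expect_identical(lbp_value(p), 255L)
  expect_error(lbp_value(matrix(0, 2, 3)), "3x3")
  # random patches, both threshold conventions
  set.seed(11)
  for (i in 1:1000) {
    patch <- matrix(sample(0:255, 9, TRUE), 3, 3)
    expect_identical(lbp_value(patch), oracle_lbp(patch))
    expect_identical(lbp_value(patch, strict = FALSE),
                     oracle_lbp(patch, strict = FALSE))
  }
})

test_that("lbp_value over all {0,128,255} patches equals the oracle exhaustively", {
  vals <- c(0L, 128L, 255L)
  grid <- as.matrix(expand.grid(rep(list(vals), 9)))
  codes_fast <- integer(nrow(grid))
  codes_oracle <- integer(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    patch <- matrix(grid[g, ], 3, 3)
    codes_fast[g] <- lbp_value(patch)
    codes_oracle[g] <- oracle_lbp(patch)
  }
  expect_identical(codes_fast, codes_oracle)
})

test_that("lbp_image computes border codes on the replicate-padded image", {
  expect_true(all(lbp_image(matrix(7L, 4, 6)) == 0L))
  set.seed(12)
  img <- matrix(sample(0:255, 25, TRUE), 5, 5)
  lm <- lbp_image(img)
  expect_identical(dim(lm), dim(img))
  pad <- img[c(1, 1:5, 5), c(1, 1:5, 5)]
  for (r in 1:5) {
    for (c in 1:5) {
      expect_identical(lm[r, c], oracle_lbp(pad[r:(r + 2), c:(c + 2)]))
    }
  }
  # degenerate single-row image must not crash
  row_img <- matrix(sample(0:255, 10, TRUE), 1, 10)
  expect_identical(dim(lbp_image(row_img)), c(1L, 10L))
  expect_error(lbp_image(matrix(numeric(0), 0, 0)), "at least one")
})

test_that("LBP codes are invariant to order-preserving intensity maps", {
  set.seed(13)
  img <- matrix(sample(0:100, 400, TRUE), 20, 20)
  # scale-and-shift that preserves all strict orderings
  img2 <- img * 2L + 10L
  expect_identical(lbp_image(img), lbp_image(img2))
})

test_that("patch descriptors conserve quadrant mass and match the crop oracle", {
  set.seed(14)
  img <- matrix(sample(0:255, 10000, TRUE), 100, 100)
  lm <- lbp_image(img)
  d <- patch_descriptor(lm, c(50, 50), 50)
  expect_length(d, 1024)
  for (q in 0:3) expect_equal(sum(d[q * 256 + 1:256]), 625)
  # constant image: all mass in bin 0 of each quadrant
  dc <- patch_descriptor(lbp_image(matrix(9L, 60, 60)), c(30, 30), 50)
  expect_equal(dc[0:3 * 256 + 1], rep(625, 4))
  expect_equal(sum(dc), 4 * 625)
  # random centers vs the independent crop-split-count oracle, including
  # centers near edges (clamped windows)
  centers <- rbind(cbind(sample(0:99, 20, TRUE), sample(0:99, 20, TRUE)),
                   c(0, 0), c(99, 99), c(0, 50), c(99, 3))
  for (i in seq_len(nrow(centers))) {
    expect_equal(patch_descriptor(lm, centers[i, ], 50),
                 oracle_descriptor(lm, centers[i, ], 50))
  }
  # batch form agrees with the single form
  dm <- patch_descriptor_matrix(lm, centers, 50)
  expect_equal(dm[3, ], patch_descriptor(lm, centers[3, ], 50))
  expect_error(patch_descriptor(lm, c(50, 50), 49), "even")
  expect_error(patch_descriptor(lm, c(200, 50), 50), "outside")
})

test_that("quadrant mass conservation holds on many random windows", {
  set.seed(15)
  img <- matrix(sample(0:255, 150 * 150, TRUE), 150, 150)
  lm <- lbp_image(img)
  for (w in c(10L, 50L)) {
    centers <- cbind(sample(0:149, 250, TRUE), sample(0:149, 250, TRUE))
    dm <- patch_descriptor_matrix(lm, centers, w)
    for (q in 0:3) {
      expect_true(all(rowSums(dm[, q * 256 + 1:256]) == (w / 2)^2))
    }
  }
})

test_that("fit_pca applies the cumulative 0.99 rule", {
  set.seed(16)
  # exact rank-2 data in 10-D with two distinct positive variances
  basis <- qr.Q(qr(matrix(rnorm(100), 10, 10)))[, 1:2]
  scores <- cbind(rnorm(300, sd = 2), rnorm(300, sd = 1))
  x <- scores %*% t(basis)
  pb <- fit_pca(x)
  expect_identical(pb$n_retained, 2L)
  # isotropic 4-D sample keeps all four directions
  x4 <- matrix(rnorm(4e4, sd = 0.5), 10000, 4)
  expect_identical(fit_pca(x4)$n_retained, 4L)
  # 1-D variance embedded in 5-D
  x1 <- outer(rnorm(100), c(1, 2, 0, -1, 3))
  expect_identical(fit_pca(x1)$n_retained, 1L)
  # eigenvalues descending, components orthonormal
  expect_true(all(diff(pb$eigenvalues) <= 1e-9))
  gram <- crossprod(pb$components)
  expect_lt(max(abs(gram - diag(nrow(gram)))), 1e-8)
  # degenerate input
  expect_error(fit_pca(matrix(1, 5, 3)), "zero total variance")
  expect_error(fit_pca(matrix(1, 1, 3)), "at least 2")
})

test_that("pca_project is the centered orthonormal projection", {
  set.seed(17)
  x <- matrix(rnorm(600), 100, 6) %*% diag(c(4, 3, 2, 0.01, 0.005, 0.001))
  pb <- fit_pca(x)
  expect_equal(pca_project(pb, pb$mean), rep(0, pb$n_retained))
  v <- pb$mean + pb$components[, 1]
  expect_equal(pca_project(pb, v),
               c(1, rep(0, pb$n_retained - 1)), tolerance = 1e-10)
  # round-trip reconstruction error bounded by residual eigenvalue mass
  xh <- matrix(rnorm(300), 50, 6) %*% diag(c(4, 3, 2, 0.01, 0.005, 0.001))
  sc <- pca_project(pb, xh)
  recon <- sweep(sc %*% t(pb$components[, 1:pb$n_retained]), 2, pb$mean, "+")
  resid_var <- mean(rowSums((xh - recon)^2))
  resid_mass <- sum(pb$eigenvalues[-(1:pb$n_retained)])
  expect_lt(resid_var, 3 * resid_mass + 1e-8)
  expect_error(pca_project(pb, rnorm(4)), "dimension")
})
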