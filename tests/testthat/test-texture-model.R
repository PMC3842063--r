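# Texture-model tests run on small synthetic problems: 2-D blob data
# standing in for projected descriptors, and tiny phantom images for the
# sample-collection geometry.

blob_grid <- list(cost_grid = 2^seq(-3, 7, by = 2),
                  gamma_grid = 2^seq(-7, 1, by = 2))

train_blob_model <- function(samp, seed = 5, folds = 5) {
  train_texture_model(samp, folds = folds,
                      cost_grid = blob_grid$cost_grid,
                      gamma_grid = blob_grid$gamma_grid, seed = seed)
}

test_that("collect_training_samples builds positives and negatives as specified", {
  set.seed(41)
  img <- matrix(sample(0:255, 80 * 80, TRUE), 80, 80)
  # boundary of 10 interior pixels on distinct, non-adjacent columns
  gt <- cbind(seq(20, 56, by = 4), seq(10, 64, by = 6))
  samp <- collect_training_samples(list(img), list(gt), window = 10,
                                   n_negatives_per_image = 50,
                                   exclusion_distance = 5, seed = 7)
  expect_s3_class(samp, "boundary_samples")
  expect_equal(sum(samp$label == "boundary"), 30) # pixel + left + right
  expect_equal(sum(samp$label == "nonboundary"), 50)
  # every negative is strictly farther than the exclusion distance
  neg <- samp$location[samp$label == "nonboundary", ]
  cheb <- sapply(seq_len(nrow(neg)), function(i) {
    min(pmax(abs(gt[, 1] - neg[i, 1]), abs(gt[, 2] - neg[i, 2])))
  })
  expect_true(all(cheb > 5))
  # deterministic given the seed
  samp2 <- collect_training_samples(list(img), list(gt), window = 10,
                                    n_negatives_per_image = 50,
                                    exclusion_distance = 5, seed = 7)
  expect_identical(samp$location, samp2$location)
  # 900 negatives per image across 2 images
  img2 <- matrix(sample(0:255, 80 * 80, TRUE), 80, 80)
  samp3 <- collect_training_samples(list(img, img2), list(gt, gt),
                                    window = 10, n_negatives_per_image = 900,
                                    exclusion_distance = 5, seed = 8)
  expect_equal(sum(samp3$label == "nonboundary"), 1800)
  # impossible exclusion region
  expect_error(
    collect_training_samples(list(img), list(gt), window = 10,
                             n_negatives_per_image = 10,
                             exclusion_distance = 200, seed = 7),
    "exclusion region")
  expect_error(
    collect_training_samples(list(img), list(gt[0, , drop = FALSE]),
                             window = 10, seed = 7),
    "empty")
})

test_that("training separates well-separated blobs and calibrates sanely", {
  samp <- two_blob_samples(n_per_class = 200, sep = 3, sd = 0.1, seed = 42)
  model <- train_blob_model(samp)
  expect_gte(model$cv$accuracy, 0.99)
  # midpoint of the class means: probability near one half
  p_mid <- texture_probability(model, rbind((samp$mu_pos + samp$mu_neg) / 2))
  expect_gt(p_mid, 0.35); expect_lt(p_mid, 0.65)
  # deep inside the boundary blob: confident
  deep <- samp$mu_pos + c(0.5, 0) # 5 sigma beyond the mean
  expect_gt(texture_probability(model, rbind(deep)), 0.9)
  deep_neg <- samp$mu_neg - c(0.5, 0)
  expect_lt(texture_probability(model, rbind(deep_neg)), 0.1)
  # training-set recall on separable data
  pred <- texture_classify(model, samp$descriptors)
  pos <- samp$label == "boundary"
  expect_gte(mean(pred[pos] == "boundary"), 0.99)
  expect_gte(mean(pred[!pos] == "nonboundary"), 0.99)
})

test_that("probabilities are proper and consistent with classification", {
  samp <- two_blob_samples(n_per_class = 150, sep = 2, sd = 0.3, seed = 43)
  model <- train_blob_model(samp)
  set.seed(44)
  probes <- matrix(rnorm(2000, sd = 1.5), ncol = 2)
  p <- texture_probability(model, probes)
  expect_true(all(p >= 0 & p <= 1))
  # binary-case coupling constraint: p1 + p2 = 1 with both non-negative
  expect_equal(p + (1 - p), rep(1, nrow(probes)))
  cls <- texture_classify(model, probes)
  expect_identical(cls == "boundary", p >= 0.5)
  # monotone in the decision value
  dv <- texture_decision(model, probes)
  o <- order(dv)
  expect_true(all(diff(p[o]) >= -1e-12))
  expect_error(texture_probability(model, rbind(c(1, 2, 3))), "dimension")
})

test_that("grid search is reproducible and stable under duplication", {
  samp <- two_blob_samples(n_per_class = 80, sep = 3, sd = 0.1, seed = 45)
  m1 <- train_blob_model(samp, seed = 9)
  m2 <- train_blob_model(samp, seed = 9)
  expect_identical(m1$cost, m2$cost)
  expect_identical(m1$gamma, m2$gamma)
  expect_identical(m1$platt, m2$platt)
  # duplicating every sample leaves the selected hyperparameters unchanged
  dup <- list(descriptors = rbind(samp$descriptors, samp$descriptors),
              label = factor(rep(as.character(samp$label), 2),
                             levels = levels(samp$label)))
  m3 <- train_blob_model(dup, seed = 9)
  expect_identical(m3$cost, m1$cost)
  expect_identical(m3$gamma, m1$gamma)
})

test_that("shuffled labels give chance-level cross-validation accuracy", {
  samp <- two_blob_samples(n_per_class = 150, sep = 3, sd = 0.1, seed = 46)
  set.seed(47)
  samp$label <- sample(samp$label)
  model <- train_blob_model(samp, seed = 10)
  expect_gte(model$cv$accuracy, 0.35)
  expect_lte(model$cv$accuracy, 0.65)
})

test_that("single-class input is rejected", {
  samp <- two_blob_samples(n_per_class = 50, seed = 48)
  keep <- samp$label == "boundary"
  expect_error(
    train_blob_model(list(descriptors = samp$descriptors[keep, ],
                          label = droplevels(samp$label[keep]))),
    "both")
})

test_that("the in-package decision function reproduces libsvm's", {
  samp <- two_blob_samples(n_per_class = 100, sep = 2, sd = 0.4, seed = 49)
  model <- train_blob_model(samp)
  # compare against e1071's own predict on the standardized scores
  z <- mammotrace::pca_project(model$pca, samp$descriptors)
  z <- scale(z, center = model$feat_center, scale = model$feat_scale)
  sv_fit <- e1071::svm(x = z, y = samp$label, kernel = "radial",
                       cost = model$cost, gamma = model$gamma, scale = FALSE)
  dv_pkg <- mammotrace:::rbf_decision(z, sv_fit$SV, sv_fit$coefs,
                                      sv_fit$rho, model$gamma)
  dv_ref <- attr(stats::predict(sv_fit, z, decision.values = TRUE),
                 "decision.values")
  expect_equal(as.numeric(dv_pkg), as.numeric(dv_ref), tolerance = 1e-10)
})
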