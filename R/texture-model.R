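# Boundary/non-boundary texture classifier: PCA-reduced LBP window
# descriptors -> RBF SVM -> calibrated class probability.
#
# The SVM decision function is f(x) = sum_i a_i exp(-gamma ||x_i - x||^2) + b
# over the support centers x_i; class probabilities are obtained by a
# logistic (Platt) sigmoid of f. With two classes the pairwise-coupling
# probability construction reduces exactly to this single sigmoid.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

CLASS_LEVELS <- c("boundary", "nonboundary")

#' Collect labeled training samples from images with ground-truth boundaries
#'
#' Positives are every ground-truth boundary pixel plus its immediate left
#' and right neighbors (deduplicated, clipped to the image). Negatives are
#' uniform random pixels, resampled until exactly `n_negatives_per_image`
#' per image lie at Chebyshev distance greater than `exclusion_distance`
#' from every boundary pixel.
#'
#' @param images list of grayscale integer matrices.
#' @param gt_boundaries list of n x 2 (row, col) ground-truth boundaries,
#'   one per image.
#' @param window even descriptor window size (default 50).
#' @param n_negatives_per_image number of negative samples per image
#'   (default 900).
#' @param exclusion_distance Chebyshev radius around the boundary within
#'   which negatives are rejected (default `window/2`).
#' @param seed integer seed; collection is deterministic given it.
#' @param strict LBP threshold convention, see [lbp_value()].
#' @return A list of class `boundary_samples` with elements `descriptors`
#'   (n x 1024 matrix), `label` (factor, levels boundary/nonboundary),
#'   `image` (integer source-image index), `location` (n x 2 matrix),
#'   `window`, `strict`.
#' @export
collect_training_samples <- function(images, gt_boundaries, window = 50L,
                                     n_negatives_per_image = 900L,
                                     exclusion_distance = window %/% 2L,
                                     seed = 1L, strict = TRUE) {
  stopifnot(length(images) == length(gt_boundaries))
  with_seed(seed, {
    desc <- list(); lab <- list(); img_id <- list(); loc <- list()
    for (i in seq_along(images)) {
      im <- images[[i]]
      validate_image(im)
      b <- gt_boundaries[[i]]
      validate_boundary(b)
      if (nrow(b) == 0L) {
        stop("ground-truth boundary ", i, " is empty", call. = FALSE)
      }
      h <- nrow(im); w <- ncol(im)
      # positives: boundary pixel and its left/right neighbors
      pos <- rbind(b,
                   cbind(b[, 1L], b[, 2L] - 1L),
                   cbind(b[, 1L], b[, 2L] + 1L))
      keep <- pos[, 2L] >= 0L & pos[, 2L] < w & pos[, 1L] >= 0L & pos[, 1L] < h
      pos <- unique(pos[keep, , drop = FALSE])
      # negatives: reject anything Chebyshev-close to the boundary
      excluded <- matrix(FALSE, h, w)
      d <- as.integer(exclusion_distance)
      for (j in seq_len(nrow(b))) {
        r <- b[j, 1L]; c <- b[j, 2L]
        excluded[max(0L, r - d):min(h - 1L, r + d) + 1L,
                 max(0L, c - d):min(w - 1L, c + d) + 1L] <- TRUE
      }
      if (all(excluded)) {
        stop("exclusion region covers image ", i,
             "; cannot draw negative samples", call. = FALSE)
      }
      n_neg <- as.integer(n_negatives_per_image)
      neg <- matrix(0L, n_neg, 2L)
      got <- 0L; tries <- 0L
      while (got < n_neg) {
        tries <- tries + 1L
        if (tries > 1000L * n_neg) {
          stop("could not draw enough negative samples for image ", i,
               call. = FALSE)
        }
        r <- sample.int(h, 1L) - 1L
        c <- sample.int(w, 1L) - 1L
        if (!excluded[r + 1L, c + 1L]) {
          got <- got + 1L
          neg[got, ] <- c(r, c)
        }
      }
      lmap <- lbp_image(im, strict = strict)
      centers <- rbind(pos, neg)
      desc[[i]] <- patch_descriptor_matrix(lmap, centers, window)
      lab[[i]] <- rep(CLASS_LEVELS, c(nrow(pos), n_neg))
      img_id[[i]] <- rep(i, nrow(centers))
      loc[[i]] <- centers
    }
    structure(list(descriptors = do.call(rbind, desc),
                   label = factor(unlist(lab), levels = CLASS_LEVELS),
                   image = unlist(img_id),
                   location = do.call(rbind, loc),
                   window = as.integer(window), strict = strict),
              class = "boundary_samples")
  })
}

# RBF decision values f(x) for a batch of points (rows of `x`), given
# support centers, their signed weights, and the offset rho (libsvm's
# convention: f = K %*% coefs - rho).
rbf_decision <- function(x, sv, coefs, rho, gamma) {
  d2 <- outer(rowSums(x^2), rowSums(sv^2), "+") - 2 * tcrossprod(x, sv)
  d2[d2 < 0] <- 0
  exp(-gamma * d2) %*% coefs - rho
}

# Platt sigmoid calibration: fit (A, B) of P(y=1|f) = 1/(1+exp(A f + B))
# by regularized maximum likelihood (Newton with backtracking, smoothed
# targets), following the standard robust formulation.
fit_platt <- function(decision, is_positive, max_iter = 200L) {
  n1 <- sum(is_positive); n0 <- sum(!is_positive)
  hi <- (n1 + 1) / (n1 + 2)
  lo <- 1 / (n0 + 2)
  t <- ifelse(is_positive, hi, lo)
  f <- as.numeric(decision)
  A <- 0; B <- log((n0 + 1) / (n1 + 1))
  nll <- function(A, B) {
    z <- A * f + B
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  val <- nll(A, B)
  for (it in seq_len(max_iter)) {
    z <- A * f + B
    p <- 1 / (1 + exp(z))
    d1 <- t - p            # note p = P(y=1) under 1/(1+e^z) with z = Af+B
    g_A <- sum(f * d1); g_B <- sum(d1)
    wq <- p * (1 - p)
    h_AA <- sum(f * f * wq) + 1e-12
    h_AB <- sum(f * wq)
    h_BB <- sum(wq) + 1e-12
    det <- h_AA * h_BB - h_AB^2
    dA <- -(h_BB * g_A - h_AB * g_B) / det
    dB <- -(h_AA * g_B - h_AB * g_A) / det
    step <- 1
    repeat {
      newA <- A + step * dA; newB <- B + step * dB
      newval <- nll(newA, newB)
      if (newval < val + 1e-10 || step < 1e-10) break
      step <- step / 2
    }
    if (abs(newval - val) < 1e-12 && max(abs(g_A), abs(g_B)) < 1e-6) {
      A <- newA; B <- newB
      break
    }
    A <- newA; B <- newB; val <- newval
  }
  list(A = A, B = B)
}

platt_probability <- function(platt, decision) {
  1 / (1 + exp(platt$A * decision + platt$B))
}

# Fit a binary RBF SVM with samples ordered so every "boundary" row comes
# first; libsvm's decision sign then corresponds to the boundary class
# consistently across fits.
fit_svm_ordered <- function(z, y, cost, gamma) {
  o <- order(y != CLASS_LEVELS[1L])
  e1071::svm(x = z[o, , drop = FALSE], y = factor(y[o], levels = CLASS_LEVELS),
             type = "C-classification", kernel = "radial",
             cost = cost, gamma = gamma, scale = FALSE)
}

stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

#' Train the boundary-texture probability model
#'
#' Fits a PCA basis on all raw descriptors (components retained up to
#' cumulative explained variance > 0.99), standardizes the projected
#' scores, selects RBF-SVM hyperparameters by stratified k-fold
#' cross-validated accuracy over a logarithmic grid, fits the final SVM on
#' all samples, and calibrates a Platt sigmoid on out-of-fold decision
#' values so that [texture_probability()] returns P(boundary | descriptor).
#'
#' @param samples a `boundary_samples` object, or any list with a numeric
#'   `descriptors` matrix and a binary `label` factor with levels
#'   `boundary`/`nonboundary`.
#' @param folds number of cross-validation folds (default 5).
#' @param cost_grid,gamma_grid logarithmic hyperparameter grids.
#' @param seed integer seed controlling fold assignment and grid-search
#'   subsampling; training is deterministic given it.
#' @param cv_subsample maximum number of samples used during the
#'   hyperparameter grid search (stratified subsample; the final model
#'   always uses all samples).
#' @param calibration_subsample maximum number of samples used for the
#'   out-of-fold Platt calibration (stratified subsample).
#' @param pca_threshold cumulative explained-variance cutoff.
#' @param class_weights optional named weights (`boundary`, `nonboundary`)
#'   passed to the SVM for imbalance handling; `NULL` (default) fits
#'   unweighted.
#' @return A list of class `texture_model`.
#' @export
train_texture_model <- function(samples, folds = 5L,
                                cost_grid = 2^seq(-5, 15, by = 2),
                                gamma_grid = 2^seq(-15, 3, by = 2),
                                seed = 1L, cv_subsample = 500L,
                                calibration_subsample = 2000L,
                                pca_threshold = 0.99, class_weights = NULL) {
  x <- samples$descriptors
  y <- factor(as.character(samples$label), levels = CLASS_LEVELS)
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (length(unique(y)) < 2L) {
    stop("both boundary and nonboundary samples are required", call. = FALSE)
  }
  if (folds < 2L) stop("`folds` must be >= 2", call. = FALSE)
  with_seed(seed, {
    pca <- fit_pca(x, threshold = pca_threshold)
    z <- pca_project(pca, x)
    feat_center <- colMeans(z)
    feat_scale <- apply(z, 2L, stats::sd)
    feat_scale[feat_scale < 1e-12] <- 1
    z <- scale(z, center = feat_center, scale = feat_scale)
    attr(z, "scaled:center") <- attr(z, "scaled:scale") <- NULL

    # -- hyperparameter grid search on a stratified subsample
    n <- nrow(z)
    strat_sub <- function(max_n) {
      if (n <= max_n) return(seq_len(n))
      sort(unlist(lapply(levels(y), function(cl) {
        idx <- which(y == cl)
        sample(idx, round(length(idx) * max_n / n))
      })))
    }
    sub <- strat_sub(cv_subsample)
    zs <- z[sub, , drop = FALSE]; ys <- y[sub]
    fold_s <- stratified_folds(ys, folds)
    best <- NULL
    cv_table <- expand.grid(gamma = gamma_grid, cost = cost_grid,
                            KEEP.OUT.ATTRS = FALSE)
    cv_table <- cv_table[, c("cost", "gamma")]
    cv_table$accuracy <- NA_real_
    for (g in seq_len(nrow(cv_table))) {
      cost <- cv_table$cost[g]; gamma <- cv_table$gamma[g]
      correct <- 0L
      for (f in seq_len(folds)) {
        tr <- fold_s != f
        m <- fit_svm_ordered(zs[tr, , drop = FALSE], ys[tr], cost, gamma)
        pred <- stats::predict(m, zs[!tr, , drop = FALSE])
        correct <- correct + sum(pred == ys[!tr])
      }
      acc <- correct / length(ys)
      cv_table$accuracy[g] <- acc
      if (is.null(best) || acc > best$accuracy + 1e-12) {
        best <- list(cost = cost, gamma = gamma, accuracy = acc)
      }
    }

    # -- out-of-fold decision values for the Platt calibration
    cal <- strat_sub(calibration_subsample)
    zc <- z[cal, , drop = FALSE]; yc <- y[cal]
    fold_cal <- stratified_folds(yc, folds)
    dec_oof <- numeric(length(cal))
    for (f in seq_len(folds)) {
      tr <- fold_cal != f
      m <- fit_svm_ordered(zc[tr, , drop = FALSE], yc[tr],
                           best$cost, best$gamma)
      dv <- rbf_decision(zc[!tr, , drop = FALSE], m$SV, m$coefs, m$rho,
                         best$gamma)
      # orient each fold model so larger decision values mean "boundary"
      te_y <- yc[!tr]
      if (mean(dv[te_y == "boundary"]) < mean(dv[te_y == "nonboundary"])) {
        dv <- -dv
      }
      dec_oof[!tr] <- dv
    }
    platt <- fit_platt(dec_oof, yc == "boundary")

    # -- final model on all samples
    wts <- if (is.null(class_weights)) NULL else class_weights
    o <- order(y != CLASS_LEVELS[1L])
    final <- e1071::svm(x = z[o, , drop = FALSE],
                        y = factor(y[o], levels = CLASS_LEVELS),
                        type = "C-classification", kernel = "radial",
                        cost = best$cost, gamma = best$gamma, scale = FALSE,
                        class.weights = wts)
    dv_train <- rbf_decision(z, final$SV, final$coefs, final$rho, best$gamma)
    flip <- if (mean(dv_train[y == "boundary"]) <
               mean(dv_train[y == "nonboundary"])) -1 else 1

    structure(list(pca = pca,
                   feat_center = feat_center, feat_scale = feat_scale,
                   sv = unname(final$SV), coefs = as.numeric(final$coefs),
                   rho = as.numeric(final$rho), gamma = best$gamma,
                   cost = best$cost, flip = flip, platt = platt,
                   window = samples$window %||% NA_integer_,
                   strict = samples$strict %||% TRUE,
                   cv = list(folds = folds, table = cv_table,
                             accuracy = best$accuracy, seed = seed)),
              class = "texture_model")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' SVM decision values for raw descriptors
#'
#' @param model a `texture_model`.
#' @param descriptors a raw descriptor vector or an n x d matrix.
#' @return Numeric decision values, oriented so larger means more
#'   boundary-like.
#' @export
texture_decision <- function(model, descriptors) {
  stopifnot(inherits(model, "texture_model"))
  z <- pca_project(model$pca, descriptors)
  if (!is.matrix(z)) z <- rbind(z)
  z <- scale(z, center = model$feat_center, scale = model$feat_scale)
  as.numeric(rbf_decision(z, model$sv, model$coefs, model$rho,
                          model$gamma)) * model$flip
}

#' Calibrated boundary probability of raw descriptors
#'
#' A strictly monotone (logistic) function of the SVM decision value;
#' probabilities of the two classes sum to one by construction.
#'
#' @inheritParams texture_decision
#' @return Probabilities in \[0, 1\] of the `boundary` class.
#' @export
texture_probability <- function(model, descriptors) {
  platt_probability(model$platt, texture_decision(model, descriptors))
}

#' Classify raw descriptors as boundary / nonboundary
#'
#' A descriptor is classified `boundary` iff its calibrated probability is
#' at least 0.5 (ties go to `boundary`).
#'
#' @inheritParams texture_decision
#' @return A factor with levels `boundary`, `nonboundary`.
#' @export
texture_classify <- function(model, descriptors) {
  p <- texture_probability(model, descriptors)
  factor(ifelse(p >= 0.5, "boundary", "nonboundary"), levels = CLASS_LEVELS)
}
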