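# Model archive: one JSON file holding the trained texture model (PCA
# basis, SVM support centers/weights, Platt calibration, feature
# configuration), the smoothness Gaussian, and the prior configuration.
# Numbers are written at full precision so probabilities round-trip
# exactly.

ARCHIVE_VERSION <- 1L

#' Bundle trained models into an archive object
#'
#' @param texture a `texture_model`.
#' @param smoothness a `smoothness_model`.
#' @param prior a [prior_config()].
#' @return A list of class `model_archive`.
#' @export
model_archive <- function(texture, smoothness, prior = prior_config()) {
  stopifnot(inherits(texture, "texture_model"),
            inherits(smoothness, "smoothness_model"),
            inherits(prior, "prior_config"))
  structure(list(format_version = ARCHIVE_VERSION, texture = texture,
                 smoothness = smoothness, prior = prior),
            class = "model_archive")
}

#' Save a model archive to a JSON file
#'
#' @param archive a [model_archive()].
#' @param path output path.
#' @export
save_model_archive <- function(archive, path) {
  stopifnot(inherits(archive, "model_archive"))
  tx <- archive$texture
  payload <- list(
    package = "mammotrace",
    format_version = ARCHIVE_VERSION,
    feature_config = list(window = tx$window, strict_lbp = tx$strict),
    texture = list(
      pca = list(mean = tx$pca$mean,
                 components = tx$pca$components[, seq_len(tx$pca$n_retained),
                                                drop = FALSE],
                 eigenvalues = tx$pca$eigenvalues,
                 n_retained = tx$pca$n_retained),
      feat_center = tx$feat_center, feat_scale = tx$feat_scale,
      sv = tx$sv, coefs = tx$coefs, rho = tx$rho, gamma = tx$gamma,
      cost = tx$cost, flip = tx$flip,
      platt = list(A = tx$platt$A, B = tx$platt$B),
      cv_accuracy = tx$cv$accuracy
    ),
    smoothness = list(mean = archive$smoothness$mean,
                      covariance = archive$smoothness$covariance,
                      epsilon = archive$smoothness$epsilon),
    prior = list(mu = archive$prior$mu, beta = archive$prior$beta)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model archive from a JSON file
#'
#' @param path path written by [save_model_archive()].
#' @return A `model_archive`.
#' @export
load_model_archive <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
                        stop("corrupt model archive: ", conditionMessage(e),
                             call. = FALSE)
                      })
  if (is.null(payload$format_version) || is.null(payload$texture) ||
      is.null(payload$smoothness)) {
    stop("corrupt model archive: missing required sections", call. = FALSE)
  }
  if (payload$format_version != ARCHIVE_VERSION) {
    stop("model archive format version ", payload$format_version,
         " not supported (expected ", ARCHIVE_VERSION, ")", call. = FALSE)
  }
  txj <- payload$texture
  n_ret <- as.integer(txj$pca$n_retained)
  comp <- matrix(as.numeric(txj$pca$components), ncol = n_ret)
  pca <- structure(list(mean = as.numeric(txj$pca$mean),
                        components = comp,
                        eigenvalues = as.numeric(txj$pca$eigenvalues),
                        n_retained = n_ret),
                   class = "pca_basis")
  texture <- structure(list(
    pca = pca,
    feat_center = as.numeric(txj$feat_center),
    feat_scale = as.numeric(txj$feat_scale),
    sv = matrix(as.numeric(txj$sv), ncol = n_ret),
    coefs = as.numeric(txj$coefs), rho = as.numeric(txj$rho),
    gamma = as.numeric(txj$gamma), cost = as.numeric(txj$cost),
    flip = as.numeric(txj$flip),
    platt = list(A = as.numeric(txj$platt$A), B = as.numeric(txj$platt$B)),
    window = as.integer(payload$feature_config$window),
    strict = isTRUE(payload$feature_config$strict_lbp),
    cv = list(accuracy = txj$cv_accuracy)
  ), class = "texture_model")
  smoothness <- structure(list(
    mean = as.numeric(payload$smoothness$mean),
    covariance = matrix(as.numeric(payload$smoothness$covariance), 2L, 2L),
    epsilon = as.numeric(payload$smoothness$epsilon)
  ), class = "smoothness_model")
  prior <- prior_config(mu = as.numeric(payload$prior$mu),
                        beta = as.numeric(payload$prior$beta))
  model_archive(texture, smoothness, prior)
}
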