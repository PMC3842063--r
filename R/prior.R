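# Laplace sharpening prior over the texture probability.
#
# Only the lower (x <= mu) branch of the Laplace density is used:
#   prior(x) = exp(-(mu - x) / beta) / (2 * beta),
# strictly increasing on [0, mu]. Applied to the texture probability it
# rewards high-probability candidates much more sharply than the logistic
# calibration alone: every 'beta' of extra texture probability multiplies
# the prior by e, independent of where on [0, mu] the step is taken.

#' Laplace prior configuration
#'
#' @param mu location of the density peak, in (0, 1\] (default 1: the peak
#'   sits at certainty).
#' @param beta scale; smaller values sharpen the preference for high
#'   texture probabilities (default 0.05).
#' @return A list of class `prior_config`.
#' @export
prior_config <- function(mu = 1, beta = 0.05) {
  if (!is.numeric(beta) || beta <= 0) stop("`beta` must be > 0", call. = FALSE)
  if (!is.numeric(mu) || mu <= 0 || mu > 1) {
    stop("`mu` must be in (0, 1]", call. = FALSE)
  }
  structure(list(mu = mu, beta = beta), class = "prior_config")
}

#' Lower-branch Laplace prior of a texture probability
#'
#' @param x texture probabilities in \[0, 1\]. Values above `mu` (possible
#'   only for user-supplied `mu < 1`) are clamped to `mu` with a warning.
#' @param config a [prior_config()].
#' @return Non-negative density values; the peak value is `1 / (2 * beta)`.
#' @export
laplace_prior <- function(x, config = prior_config()) {
  stopifnot(inherits(config, "prior_config"))
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("`x` must be a probability in [0, 1]", call. = FALSE)
  }
  if (any(x > config$mu)) {
    warning("texture probability above mu = ", config$mu, "; clamped")
    x <- pmin(x, config$mu)
  }
  exp(-(config$mu - x) / config$beta) / (2 * config$beta)
}
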