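# Training objective: a Charbonnier penalty on the SR luminance residual
# plus a binary cross-entropy term on the parsing map, combined as
# L = rho(sr_hat - sr) + lambda * BCE(map_hat, map), averaged over pixels and
# the minibatch. The Charbonnier function rho(x) = sqrt(x^2 + eps^2) is a
# smooth robust surrogate for |x| that is less prone to over-smoothing than
# squared error; eps = 1e-3 by default. lambda = 1 by default, making the
# weighted and unweighted forms of the total loss coincide.

#' Loss configuration
#'
#' @param epsilon Charbonnier constant (> 0, default `1e-3`).
#' @param lambda weight of the parsing-map BCE term (>= 0, default 1).
#' @return a `loss_config` list.
#' @export
loss_config <- function(epsilon = 1e-3, lambda = 1) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (lambda < 0) stop("lambda must be >= 0")
  structure(list(epsilon = epsilon, lambda = lambda), class = "loss_config")
}

#' Charbonnier penalty
#'
#' Elementwise `sqrt(x^2 + epsilon^2)` averaged over all entries: a smooth
#' upper bound on `|x|` with minimum value `epsilon` at zero residual.
#'
#' @param residual numeric array/matrix of residuals.
#' @param epsilon smoothing constant (> 0).
#' @return scalar mean penalty.
#' @examples
#' charbonnier(matrix(0, 2, 2))           # exactly 1e-3
#' charbonnier(matrix(1, 2, 2))           # sqrt(1 + 1e-6)
#' @export
charbonnier <- function(residual, epsilon = 1e-3) {
  if (anyNA(residual) || any(!is.finite(residual)))
    stop("non-finite residual passed to charbonnier()")
  if (epsilon <= 0) stop("epsilon must be > 0")
  mean(sqrt(residual^2 + epsilon^2))
}

charbonnier_grad <- function(residual, epsilon = 1e-3) {
  residual / sqrt(residual^2 + epsilon^2) / length(residual)
}

.bce_clamp <- 1e-7

#' Binary cross-entropy between parsing maps
#'
#' Mean over all pixels and channels of
#' `-(t * log(p) + (1 - t) * log(1 - p))`, with predictions clamped to
#' `[1e-7, 1 - 1e-7]`. The prediction is a per-pixel class distribution (the
#' softmax output of the prior network); the target is one-hot.
#'
#' @param predicted numeric array of probabilities.
#' @param target numeric array of the same shape (one-hot ground truth).
#' @return scalar mean BCE.
#' @examples
#' p <- array(0.5, c(2, 2, 3)); t <- array(0, c(2, 2, 3)); t[, , 3] <- 1
#' bce(p, t)   # log(2)
#' @export
bce <- function(predicted, target) {
  if (!identical(dim(predicted), dim(target)))
    stop("predicted and target maps have different shapes")
  p <- pmin(pmax(predicted, .bce_clamp), 1 - .bce_clamp)
  -mean(target * log(p) + (1 - target) * log1p(-p))
}

bce_grad <- function(predicted, target) {
  p <- pmin(pmax(predicted, .bce_clamp), 1 - .bce_clamp)
  g <- (-target / p + (1 - target) / (1 - p)) / length(p)
  g[predicted < .bce_clamp | predicted > 1 - .bce_clamp] <- 0  # clamped region
  g
}

#' Total training loss (Charbonnier + lambda * BCE)
#'
#' @param sr_pred,sr_target predicted and ground-truth HR luminance.
#' @param map_pred,map_target predicted and ground-truth parsing maps; both
#'   `NULL` for the none-prior variant, in which case the BCE term is 0.
#' @param config a [loss_config()].
#' @return list with `total`, `sr` (Charbonnier component) and `prior` (BCE
#'   component, before weighting).
#' @export
total_loss <- function(sr_pred, sr_target, map_pred = NULL, map_target = NULL,
                       config = loss_config()) {
  if (!identical(dim(sr_pred), dim(sr_target)))
    stop("SR prediction and target have different shapes")
  l_sr <- charbonnier(sr_pred - sr_target, config$epsilon)
  l_prior <- if (is.null(map_pred)) 0 else bce(map_pred, map_target)
  list(total = l_sr + config$lambda * l_prior, sr = l_sr, prior = l_prior)
}
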