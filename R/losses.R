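# Multi-task segmentation losses: Tversky (overlap with asymmetric
# FP/FN weighting), focal (hard-voxel-weighted cross-entropy) on the mask
# head, and mean squared error on the vector-field head.

#' Loss weights and hyper-parameters
#'
#' @param lambda_tversky,lambda_focal,lambda_mse Nonnegative weights of the
#'   three loss terms (defaults 1, 10, 10).
#' @param alpha_fn,alpha_fp Tversky trade-off between false negatives and
#'   false positives; must sum to 1 (defaults 0.3, 0.7).
#' @param beta Focal class-balance weight in (0, 1) (default 0.8).
#' @param gamma Focal modulating exponent >= 0 (default 2).
#' @return A list of class `loss_weights`.
#' @export
loss_weights <- function(lambda_tversky = 1, lambda_focal = 10,
                         lambda_mse = 10, alpha_fn = 0.3, alpha_fp = 0.7,
                         beta = 0.8, gamma = 2) {
  stopifnot(lambda_tversky >= 0, lambda_focal >= 0, lambda_mse >= 0,
            abs(alpha_fn + alpha_fp - 1) < 1e-12,
            beta > 0, beta < 1, gamma >= 0)
  structure(list(lambda_tversky = lambda_tversky,
                 lambda_focal = lambda_focal, lambda_mse = lambda_mse,
                 alpha_fn = alpha_fn, alpha_fp = alpha_fp,
                 beta = beta, gamma = gamma),
            class = "loss_weights")
}

#' Tversky loss
#'
#' `1 - TI` where `TI = I / (I + alpha_fn * FN + alpha_fp * FP)`,
#' `I = sum(s * p)`, `FN = sum(s * (1 - p))`, `FP = sum((1 - s) * p)`,
#' with a small smoothing constant added to numerator and denominator.
#' Zero at the perfect prediction; `alpha_fn`/`alpha_fp` trade off
#' sensitivity against precision.
#'
#' @param s Binary target (values in \{0, 1\}).
#' @param p Predicted foreground probabilities in \[0, 1\], same shape.
#' @param alpha_fn,alpha_fp Trade-off weights summing to 1.
#' @param eps Smoothing constant.
#' @return Nonnegative scalar.
#' @export
tversky_loss <- function(s, p, alpha_fn = 0.3, alpha_fp = 0.7, eps = 1e-6) {
  if (!identical(dim(s), dim(p)) || length(s) != length(p))
    stop("shape mismatch between target and prediction", call. = FALSE)
  inter <- sum(s * p)
  fn <- sum(s * (1 - p))
  fp <- sum((1 - s) * p)
  1 - (inter + eps) / (inter + alpha_fn * fn + alpha_fp * fp + eps)
}

#' Focal loss
#'
#' `-(1/P) * sum( beta * s * (1-p)^gamma * log(p)
#'              + (1-beta) * (1-s) * p^gamma * log(1-p) )`
#' with probabilities clipped away from 0 and 1. At `gamma = 0`,
#' `beta = 0.5` this is half the mean binary cross-entropy.
#'
#' @inheritParams tversky_loss
#' @param beta Class-balance weight in (0, 1).
#' @param gamma Modulating exponent >= 0.
#' @param clip Probability clipping constant.
#' @return Nonnegative scalar.
#' @export
focal_loss <- function(s, p, beta = 0.8, gamma = 2, clip = 1e-7) {
  if (!identical(dim(s), dim(p)) || length(s) != length(p))
    stop("shape mismatch between target and prediction", call. = FALSE)
  p <- pmin(pmax(p, clip), 1 - clip)
  -mean(beta * s * (1 - p)^gamma * log(p) +
          (1 - beta) * (1 - s) * p^gamma * log(1 - p))
}

#' Mean-squared-error vector-field loss
#'
#' Mean over all scalar entries (voxels x 3 components) of the squared
#' difference between target and predicted vector fields.
#'
#' @param v Target vector field (X, Y, Z, 3).
#' @param vhat Predicted vector field, same shape.
#' @return Nonnegative scalar.
#' @export
mse_vector_loss <- function(v, vhat) {
  if (!identical(dim(v), dim(vhat)))
    stop("shape mismatch between vector fields", call. = FALSE)
  mean((v - vhat)^2)
}

#' Combined multi-task loss
#'
#' `lambda_tversky * L_TL + lambda_focal * L_FL + lambda_mse * L_MSE`.
#'
#' @inheritParams tversky_loss
#' @param v,vhat Target and predicted vector fields.
#' @param w A [loss_weights()].
#' @return Nonnegative scalar.
#' @export
combined_loss <- function(s, p, v, vhat, w = loss_weights()) {
  w$lambda_tversky * tversky_loss(s, p, w$alpha_fn, w$alpha_fp) +
    w$lambda_focal * focal_loss(s, p, w$beta, w$gamma) +
    w$lambda_mse * mse_vector_loss(v, vhat)
}

# Analytic gradients of the combined loss with respect to the predicted
# probabilities and vector field, used by the trainer.
combined_loss_grad <- function(s, p, v, vhat, w, clip = 1e-7, eps = 1e-6) {
  pc <- pmin(pmax(p, clip), 1 - clip)
  inter <- sum(s * pc)
  D <- inter + w$alpha_fn * sum(s * (1 - pc)) +
    w$alpha_fp * sum((1 - s) * pc)
  # d(1 - TI)/dp
  dnum <- s
  dden <- s - w$alpha_fn * s + w$alpha_fp * (1 - s)
  dtv <- -(dnum * (D + eps) - (inter + eps) * dden) / (D + eps)^2
  P <- length(s)
  dfl <- -(1 / P) * (
    w$beta * s * (-w$gamma * (1 - pc)^(pmax(w$gamma - 1, 0)) * log(pc) +
                    (1 - pc)^w$gamma / pc) +
      (1 - w$beta) * (1 - s) * (w$gamma * pc^(pmax(w$gamma - 1, 0)) *
                                  log(1 - pc) - pc^w$gamma / (1 - pc)))
  dp <- w$lambda_tversky * dtv + w$lambda_focal * dfl
  dv <- w$lambda_mse * 2 * (vhat - v) / length(v)
  list(dprob = dp, dvec = dv)
}
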