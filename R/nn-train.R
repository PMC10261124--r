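# Training loop (Adam, constant learning rate) and prediction methods for
# the multi-task 3D U-Net.

# flatten the model into a list of layer environments
collect_layers <- function(m) {
  out <- list()
  add <- function(x) out[[length(out) + 1L]] <<- x
  for (e in m$stem) add(e)
  for (l in seq_len(m$levels)) {
    rb <- m$enc_res[[l]]
    if (!is.null(rb)) for (e in rb$inner) add(e)
  }
  for (l in seq_len(m$levels - 1L)) {
    for (e in m$down[[l]]) add(e)
    for (e in m$up[[l]]) add(e)
    if (!is.null(m$att[[l]])) add(m$att[[l]])
    for (e in m$dec[[l]]) add(e)
  }
  add(m$head_mask)
  add(m$head_vec)
  out
}

# (parameter, gradient) field pairs per layer type
.param_map <- list(
  conv3 = list(c("W", "dW"), c("b", "db")),
  bn = list(c("g", "dg"), c("b", "db")),
  dense = list(c("W", "dW"), c("b", "db")),
  attention = list(c("Ws", "dWs"), c("Wg", "dWg"), c("b1", "db1"),
                   c("Wpsi", "dWpsi"), c("b2", "db2")))

# enumerate parameter slots: list(env, par, grad, idx) with idx into a
# list-valued parameter (conv kernels) or NA
param_slots <- function(m) {
  slots <- list()
  for (e in collect_layers(m)) {
    pm <- .param_map[[e$type]]
    if (is.null(pm)) next
    for (pg in pm) {
      val <- e[[pg[1]]]
      if (is.list(val)) {
        for (i in seq_along(val))
          slots[[length(slots) + 1L]] <-
            list(env = e, par = pg[1], grad = pg[2], idx = i)
      } else {
        slots[[length(slots) + 1L]] <-
          list(env = e, par = pg[1], grad = pg[2], idx = NA_integer_)
      }
    }
  }
  slots
}

slot_get <- function(s, field) {
  v <- s$env[[field]]
  if (!is.na(s$idx)) v[[s$idx]] else v
}

slot_set <- function(s, value) {
  if (!is.na(s$idx)) s$env[[s$par]][[s$idx]] <- value
  else s$env[[s$par]] <- value
  invisible(NULL)
}

#' Number of trainable parameters
#' @param m A [nn_unet3d()] model.
#' @return Integer count.
#' @export
n_params <- function(m) {
  sum(vapply(param_slots(m), function(s) length(slot_get(s, s$par)), 0))
}

#' Train the multi-task 3D U-Net
#'
#' Minimizes the combined Tversky + focal + MSE loss with Adam at a
#' constant learning rate. Each sample supplies an intensity volume
#' (min-max normalized to \[0, 1\] per volume) and an instance label
#' volume; the binary mask target is `labels > 0` and the vector-field
#' target is computed with [generate_vector_field()] (or passed
#' precomputed as `vec`). Patch dimensions must be divisible by
#' `2^(levels-1)`.
#'
#' @param m A [nn_unet3d()] model (updated in place and returned).
#' @param data List of samples, each `list(intensity =, labels =, vec =)`
#'   (`vec` optional).
#' @param epochs Training epochs (>= 1).
#' @param lr Learning rate (default 0.001).
#' @param weights A [loss_weights()].
#' @param seed Optional seed (shuffling order).
#' @param shuffle Reshuffle sample order each epoch.
#' @param verbose Print per-epoch losses.
#' @return The model, with `$history` holding per-epoch mean combined loss.
#' @export
train_unet3d <- function(m, data, epochs = 100L, lr = 1e-3,
                         weights = loss_weights(), seed = NULL,
                         shuffle = TRUE, verbose = FALSE) {
  stopifnot(inherits(m, "nuc_unet3d"), epochs >= 1)
  if (length(data) == 0L) stop("empty training set", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  prep <- lapply(data, function(smp) {
    x <- normalize01(smp$intensity)
    s <- matrix(as.numeric(smp$labels > 0), length(smp$labels), 1L)
    vf <- if (!is.null(smp$vec)) smp$vec
    else generate_vector_field(smp$labels)
    list(x = x, s = s, v = matrix(vf, ncol = 3L))
  })
  slots <- param_slots(m)
  mt <- lapply(slots, function(s) slot_get(s, s$par) * 0)
  vt <- mt
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- if (shuffle) sample(length(prep)) else seq_along(prep)
    ep_loss <- 0
    for (i in ord) {
      smp <- prep[[i]]
      out <- model_forward(m, smp$x, train = TRUE)
      loss <- combined_loss(smp$s, out$prob, smp$v, out$vec, weights)
      if (!is.finite(loss))
        stop("non-finite loss at epoch ", ep, ", sample ", i,
             " (lr too high or degenerate input)", call. = FALSE)
      ep_loss <- ep_loss + loss
      g <- combined_loss_grad(smp$s, out$prob, smp$v, out$vec, weights)
      model_backward(m, g$dprob, g$dvec)
      step <- step + 1L
      for (k in seq_along(slots)) {
        s <- slots[[k]]
        gr <- slot_get(s, s$grad)
        mt[[k]] <- b1 * mt[[k]] + (1 - b1) * gr
        vt[[k]] <- b2 * vt[[k]] + (1 - b2) * gr^2
        mhat <- mt[[k]] / (1 - b1^step)
        vhat <- vt[[k]] / (1 - b2^step)
        slot_set(s, slot_get(s, s$par) - lr * mhat / (sqrt(vhat) + eps))
      }
    }
    m$history <- c(m$history, ep_loss / length(prep))
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f", ep, ep_loss / length(prep)))
  }
  invisible(m)
}

normalize01 <- function(vol) {
  r <- range(vol)
  if (r[2] > r[1]) (vol - r[1]) / (r[2] - r[1]) else vol * 0
}

#' Predict mask probabilities and vector field for a volume
#'
#' @param object A trained [nn_unet3d()] model.
#' @param vol Intensity volume (X, Y, Z); dimensions must be divisible by
#'   `2^(levels-1)` (use [predict_tiled()] with [as_predictor()] for
#'   arbitrary sizes).
#' @param ... Unused.
#' @return List with `prob` (X, Y, Z array in \[0, 1\]) and `vec`
#'   (X, Y, Z, 3 array of unbounded offsets).
#' @export
predict.nuc_unet3d <- function(object, vol, ...) {
  x <- normalize01(vol)
  out <- model_forward(object, x, train = FALSE)
  list(prob = array(out$prob, dim(vol)),
       vec = array(out$vec, c(dim(vol), 3L)))
}

#' Wrap a model as a tiling-compatible predictor
#'
#' @param m A trained model.
#' @return `function(vol) list(prob =, vec =)` for [predict_tiled()].
#' @export
as_predictor <- function(m) function(vol) predict(m, vol)

#' @export
print.nuc_unet3d <- function(x, ...) {
  cat("Multi-task 3D U-Net:", x$levels, "levels, base width", x$base_width,
      "\n  attention gates:", x$use_attention,
      " residual blocks:", x$use_residual,
      "\n  trainable parameters:", n_params(x), "\n")
  if (length(x$history) > 0)
    cat("  trained", length(x$history), "epochs; last loss",
        sprintf("%.5f", tail(x$history, 1)), "\n")
  invisible(x)
}
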