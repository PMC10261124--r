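# Natively implemented trainable 3D U-Net with a binary-mask head and a
# 3-channel vector-field head.
#
# Feature maps are (n_voxels x channels) matrices in column-major spatial
# order; convolutions are evaluated as 27 shifted GEMMs (one per kernel
# offset) so all heavy arithmetic runs in BLAS. Layers are small mutable
# environments holding parameters, gradients and forward caches; the
# network graph (skips, attention gates, concatenations) is wired
# explicitly in the model forward/backward.

.shift_cache <- new.env(parent = emptyenv())

# 27 gather maps (one per 3x3x3 offset) for dims dm; sentinel n+1 marks
# zero padding.
conv_maps <- function(dm) {
  key <- paste(dm, collapse = "x")
  got <- .shift_cache[[key]]
  if (!is.null(got)) return(got)
  X <- dm[1]; Y <- dm[2]; Z <- dm[3]
  n <- prod(dm)
  cx <- rep.int(seq_len(X), Y * Z)
  cy <- rep.int(rep(seq_len(Y), each = X), Z)
  cz <- rep(seq_len(Z), each = X * Y)
  maps <- vector("list", 27L)
  k <- 0L
  for (oz in -1:1) for (oy in -1:1) for (ox in -1:1) {
    k <- k + 1L
    sx <- cx + ox; sy <- cy + oy; sz <- cz + oz
    ok <- sx >= 1L & sx <= X & sy >= 1L & sy <= Y & sz >= 1L & sz <= Z
    m <- rep.int(n + 1L, n)
    m[ok] <- sx[ok] + X * (sy[ok] - 1L) + X * Y * (sz[ok] - 1L)
    maps[[k]] <- m
  }
  .shift_cache[[key]] <- maps
  maps
}

# index of voxels kept by a stride-2 subsampling of dims dm
stride2_sel <- function(dm) {
  key <- paste("s2", paste(dm, collapse = "x"))
  got <- .shift_cache[[key]]
  if (!is.null(got)) return(got)
  X <- dm[1]; Y <- dm[2]; Z <- dm[3]
  cx <- rep.int(seq_len(X), Y * Z)
  cy <- rep.int(rep(seq_len(Y), each = X), Z)
  cz <- rep(seq_len(Z), each = X * Y)
  sel <- which(cx %% 2L == 1L & cy %% 2L == 1L & cz %% 2L == 1L)
  .shift_cache[[key]] <- sel
  sel
}

# rows of the 2x-upsampled grid that carry the coarse voxels
upsample_idx <- function(dm_coarse) {
  key <- paste("up", paste(dm_coarse, collapse = "x"))
  got <- .shift_cache[[key]]
  if (!is.null(got)) return(got)
  X <- dm_coarse[1]; Y <- dm_coarse[2]; Z <- dm_coarse[3]
  cx <- rep.int(seq_len(X), Y * Z)
  cy <- rep.int(rep(seq_len(Y), each = X), Z)
  cz <- rep(seq_len(Z), each = X * Y)
  X2 <- 2L * X; Y2 <- 2L * Y
  idx <- (2L * cx - 1L) + X2 * (2L * cy - 2L) + X2 * Y2 * (2L * cz - 2L)
  .shift_cache[[key]] <- idx
  idx
}

conv3_forward <- function(x, dm, W, b) {
  n <- nrow(x)
  maps <- conv_maps(dm)
  xa <- rbind(x, 0)
  y <- matrix(b, n, length(b), byrow = TRUE)
  for (k in 1:27) y <- y + xa[maps[[k]], , drop = FALSE] %*% W[[k]]
  y
}

conv3_backward <- function(dy, x, dm, W) {
  n <- nrow(x)
  maps <- conv_maps(dm)
  xa <- rbind(x, 0)
  dxa <- matrix(0, n + 1L, ncol(x))
  dW <- vector("list", 27L)
  scratch <- matrix(0, n + 1L, ncol(x))
  for (k in 1:27) {
    xs <- xa[maps[[k]], , drop = FALSE]
    dW[[k]] <- crossprod(xs, dy)
    scratch[] <- 0
    scratch[maps[[k]], ] <- dy %*% t(W[[k]])
    dxa <- dxa + scratch
  }
  list(dx = dxa[seq_len(n), , drop = FALSE], dW = dW, db = colSums(dy))
}

# ---- layer constructors -------------------------------------------------

new_conv3 <- function(in_ch, out_ch, stride = 1L) {
  lim <- sqrt(6 / (27 * in_ch))
  e <- new.env(parent = emptyenv())
  e$type <- "conv3"
  e$W <- lapply(1:27, function(k)
    matrix(runif(in_ch * out_ch, -lim, lim), in_ch, out_ch))
  e$b <- numeric(out_ch)
  e$stride <- as.integer(stride)
  e
}

new_bn <- function(ch, momentum = 0.1, eps = 1e-5) {
  e <- new.env(parent = emptyenv())
  e$type <- "bn"
  e$g <- rep(1, ch); e$b <- rep(0, ch)
  e$rm <- rep(0, ch); e$rv <- rep(1, ch)
  e$momentum <- momentum; e$eps <- eps
  e
}

new_act <- function(alpha = 0.1) {
  e <- new.env(parent = emptyenv())
  e$type <- "act"; e$alpha <- alpha
  e
}

new_dense <- function(in_ch, out_ch) {
  lim <- sqrt(6 / in_ch)
  e <- new.env(parent = emptyenv())
  e$type <- "dense"
  e$W <- matrix(runif(in_ch * out_ch, -lim, lim), in_ch, out_ch)
  e$b <- numeric(out_ch)
  e
}

new_attention <- function(ch) {
  inter <- max(1L, ch %/% 2L)
  lim <- sqrt(6 / ch)
  e <- new.env(parent = emptyenv())
  e$type <- "attention"
  e$Ws <- matrix(runif(ch * inter, -lim, lim), ch, inter)
  e$Wg <- matrix(runif(ch * inter, -lim, lim), ch, inter)
  e$b1 <- numeric(inter)
  e$Wpsi <- matrix(runif(inter, -sqrt(6 / inter), sqrt(6 / inter)), inter, 1)
  e$b2 <- 0
  e
}

# ---- layer forward/backward --------------------------------------------

layer_forward <- function(e, x, dm, train = TRUE) {
  switch(e$type,
    conv3 = {
      e$x <- x; e$dm <- dm
      y <- conv3_forward(x, dm, e$W, e$b)
      if (e$stride == 2L) {
        sel <- stride2_sel(dm)
        e$sel <- sel
        y <- y[sel, , drop = FALSE]
        dm <- (dm + 1L) %/% 2L
      }
      list(y = y, dm = dm)
    },
    bn = {
      if (train) {
        mu <- colMeans(x)
        xc <- sweep(x, 2L, mu)
        v <- colMeans(xc^2)
        istd <- 1 / sqrt(v + e$eps)
        xhat <- sweep(xc, 2L, istd, "*")
        e$rm <- (1 - e$momentum) * e$rm + e$momentum * mu
        e$rv <- (1 - e$momentum) * e$rv + e$momentum * v
        e$xhat <- xhat; e$istd <- istd
        y <- sweep(sweep(xhat, 2L, e$g, "*"), 2L, e$b, "+")
      } else {
        xhat <- sweep(sweep(x, 2L, e$rm), 2L, 1 / sqrt(e$rv + e$eps), "*")
        y <- sweep(sweep(xhat, 2L, e$g, "*"), 2L, e$b, "+")
      }
      list(y = y, dm = dm)
    },
    act = {
      e$mask_pos <- x > 0
      list(y = ifelse(e$mask_pos, x, e$alpha * x), dm = dm)
    },
    dense = {
      e$x <- x
      list(y = sweep(x %*% e$W, 2L, e$b, "+"), dm = dm)
    },
    stop("unknown layer type ", e$type))
}

layer_backward <- function(e, dy) {
  switch(e$type,
    conv3 = {
      if (e$stride == 2L) {
        full <- matrix(0, prod(e$dm), ncol(dy))
        full[e$sel, ] <- dy
        dy <- full
      }
      g <- conv3_backward(dy, e$x, e$dm, e$W)
      e$dW <- g$dW; e$db <- g$db
      g$dx
    },
    bn = {
      n <- nrow(dy)
      dxhat <- sweep(dy, 2L, e$g, "*")
      m1 <- colMeans(dxhat)
      m2 <- colMeans(dxhat * e$xhat)
      dx <- sweep(dxhat, 2L, m1) - sweep(e$xhat, 2L, m2, "*")
      dx <- sweep(dx, 2L, e$istd, "*")
      e$dg <- colSums(dy * e$xhat); e$db <- colSums(dy)
      dx
    },
    act = ifelse(e$mask_pos, dy, e$alpha * dy),
    dense = {
      e$dW <- crossprod(e$x, dy); e$db <- colSums(dy)
      dy %*% t(e$W)
    },
    stop("unknown layer type ", e$type))
}

attention_forward <- function(e, s, g) {
  a1 <- sweep(s %*% e$Ws + g %*% e$Wg, 2L, e$b1, "+")
  r <- pmax(a1, 0)
  att <- 1 / (1 + exp(-(r %*% e$Wpsi + e$b2)))
  e$s <- s; e$g_in <- g; e$a1 <- a1; e$r <- r; e$att <- att
  s * as.vector(att)
}

attention_backward <- function(e, dy) {
  ds <- dy * as.vector(e$att)
  datt <- rowSums(dy * e$s)
  dpre <- datt * as.vector(e$att) * (1 - as.vector(e$att))
  e$dWpsi <- crossprod(e$r, dpre)
  e$db2 <- sum(dpre)
  dr <- dpre %*% t(e$Wpsi)
  da1 <- dr * (e$a1 > 0)
  e$dWs <- crossprod(e$s, da1)
  e$dWg <- crossprod(e$g_in, da1)
  e$db1 <- colSums(da1)
  ds <- ds + da1 %*% t(e$Ws)
  dg <- da1 %*% t(e$Wg)
  list(ds = ds, dg = dg)
}

# sequential composite
seq_forward <- function(layers, x, dm, train) {
  for (e in layers) {
    out <- layer_forward(e, x, dm, train)
    x <- out$y; dm <- out$dm
  }
  list(y = x, dm = dm)
}

seq_backward <- function(layers, dy) {
  for (e in rev(layers)) dy <- layer_backward(e, dy)
  dy
}

conv_block <- function(in_ch, out_ch, stride = 1L)
  list(new_conv3(in_ch, out_ch, stride), new_bn(out_ch), new_act())

# residual block: conv-bn-act-conv-bn, add input, act
res_block_forward <- function(blk, x, dm, train) {
  out <- seq_forward(blk$inner, x, dm, train)
  pre <- out$y + x
  blk$final$mask_pos <- pre > 0
  list(y = ifelse(blk$final$mask_pos, pre, blk$final$alpha * pre), dm = dm)
}

res_block_backward <- function(blk, dy) {
  dpre <- ifelse(blk$final$mask_pos, dy, blk$final$alpha * dy)
  dx <- seq_backward(blk$inner, dpre)
  dx + dpre
}

new_res_block <- function(ch) {
  final <- new.env(parent = emptyenv())
  final$alpha <- 0.1
  list(inner = c(conv_block(ch, ch), list(new_conv3(ch, ch), new_bn(ch))),
       final = final)
}

#' Build the multi-task 3D U-Net
#'
#' Encoder: per level a 3x3x3 conv block (conv + batch norm + leaky ReLU)
#' and a residual block, with stride-2 conv blocks for downsampling.
#' Decoder: transpose-conv blocks (2x upsampling), attention-gated skip
#' concatenation, and conv blocks. Two heads: a single-channel logistic
#' mask head and a 3-channel linear vector-field head (no squashing — the
#' regressed offsets are unbounded).
#'
#' @param levels Number of resolution levels (>= 2).
#' @param base_width Channels at the finest level (>= 4).
#' @param use_attention Gate the skip connections (default TRUE).
#' @param use_residual Include residual blocks (default TRUE).
#' @param mask_bias_prior Expected foreground fraction used to initialize
#'   the mask-head bias at the prior logit (the standard initialization
#'   for class-imbalanced segmentation); NULL for a zero bias.
#' @param seed Optional seed for weight initialization.
#' @return An object of class `nuc_unet3d`.
#' @export
nn_unet3d <- function(levels = 3L, base_width = 8L, use_attention = TRUE,
                      use_residual = TRUE, mask_bias_prior = 0.05,
                      seed = NULL) {
  stopifnot(levels >= 2L, base_width >= 4L)
  if (!is.null(seed)) set.seed(seed)
  w <- function(l) base_width * 2L^l
  m <- new.env(parent = emptyenv())
  m$levels <- as.integer(levels)
  m$base_width <- as.integer(base_width)
  m$use_attention <- use_attention
  m$use_residual <- use_residual
  m$stem <- conv_block(1L, w(0))
  m$enc_res <- lapply(0:(levels - 1L), function(l)
    if (use_residual) new_res_block(w(l)) else NULL)
  m$down <- lapply(seq_len(levels - 1L), function(l)
    conv_block(w(l - 1L), w(l), stride = 2L))
  m$up <- lapply(seq_len(levels - 1L), function(l)
    conv_block(w(l), w(l - 1L)))          # applied after zero-stuffing
  m$att <- lapply(seq_len(levels - 1L), function(l)
    if (use_attention) new_attention(w(l - 1L)) else NULL)
  m$dec <- lapply(seq_len(levels - 1L), function(l)
    conv_block(2L * w(l - 1L), w(l - 1L)))
  m$head_mask <- new_dense(w(0), 1L)
  if (!is.null(mask_bias_prior))
    m$head_mask$b[] <- log(mask_bias_prior / (1 - mask_bias_prior))
  m$head_vec <- new_dense(w(0), 3L)
  # zero-init the closing batch-norm gain of each residual block so every
  # block starts as the identity (stabilizes early optimization)
  if (use_residual)
    for (rb in m$enc_res) rb$inner[[5]]$g[] <- 0
  m$history <- numeric(0)
  class(m) <- "nuc_unet3d"
  m
}

model_forward <- function(m, vol, train = TRUE) {
  dm <- dim(vol)
  if (any(dm %% 2L^(m$levels - 1L) != 0L))
    stop("input shape must be divisible by ", 2L^(m$levels - 1L),
         " per axis (pad via the tiling module)", call. = FALSE)
  x <- matrix(as.vector(vol), prod(dm), 1L)
  out <- seq_forward(m$stem, x, dm, train)
  if (m$use_residual)
    out <- res_block_forward(m$enc_res[[1]], out$y, out$dm, train)
  skips <- list(out)
  for (l in seq_len(m$levels - 1L)) {
    out <- seq_forward(m$down[[l]], out$y, out$dm, train)
    if (m$use_residual)
      out <- res_block_forward(m$enc_res[[l + 1L]], out$y, out$dm, train)
    skips[[l + 1L]] <- out
  }
  m$dec_cache <- vector("list", m$levels - 1L)
  for (l in rev(seq_len(m$levels - 1L))) {
    dm_c <- out$dm
    up_idx <- upsample_idx(dm_c)
    dm_f <- 2L * dm_c
    stuffed <- matrix(0, prod(dm_f), ncol(out$y))
    stuffed[up_idx, ] <- out$y
    up <- seq_forward(m$up[[l]], stuffed, dm_f, train)
    s <- skips[[l]]$y
    s_used <- if (m$use_attention)
      attention_forward(m$att[[l]], s, up$y) else s
    cat_in <- cbind(up$y, s_used)
    out <- seq_forward(m$dec[[l]], cat_in, dm_f, train)
    m$dec_cache[[l]] <- list(dm_c = dm_c, up_idx = up_idx,
                             nch_up = ncol(up$y))
  }
  logits <- layer_forward(m$head_mask, out$y, out$dm, train)$y
  prob <- 1 / (1 + exp(-logits))
  vec <- layer_forward(m$head_vec, out$y, out$dm, train)$y
  m$prob_cache <- prob
  list(prob = prob, vec = vec, dm = out$dm)
}

model_backward <- function(m, dprob, dvec) {
  dlogits <- dprob * m$prob_cache * (1 - m$prob_cache)
  gD <- layer_backward(m$head_mask, dlogits) +
    layer_backward(m$head_vec, dvec)
  # decoder sweep (finest to coarsest), collecting skip gradients
  gskip <- vector("list", m$levels)
  for (l in seq_len(m$levels - 1L)) {
    cache <- m$dec_cache[[l]]
    dcat <- seq_backward(m$dec[[l]], gD)
    dup <- dcat[, seq_len(cache$nch_up), drop = FALSE]
    ds_used <- dcat[, -seq_len(cache$nch_up), drop = FALSE]
    if (m$use_attention) {
      ab <- attention_backward(m$att[[l]], ds_used)
      gskip[[l]] <- ab$ds
      dup <- dup + ab$dg
    } else gskip[[l]] <- ds_used
    dstuffed <- seq_backward(m$up[[l]], dup)
    gD <- dstuffed[cache$up_idx, , drop = FALSE]
  }
  # encoder sweep (coarsest to finest), merging skip gradients
  acc <- gD
  for (l in rev(seq_len(m$levels - 1L))) {
    if (m$use_residual)
      acc <- res_block_backward(m$enc_res[[l + 1L]], acc)
    acc <- seq_backward(m$down[[l]], acc)
    acc <- acc + gskip[[l]]
  }
  if (m$use_residual) acc <- res_block_backward(m$enc_res[[1]], acc)
  invisible(seq_backward(m$stem, acc))
}
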