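# Divide-and-conquer inference: K-sized windows at stride K/2, each padded
# by K/4 per border (reflection supplies out-of-volume voxels); only the
# centered K/2 interior of every window is written to the global output,
# with first/last interiors extended to the volume edges so the interiors
# partition the volume exactly.

# Per-axis window starts and interior cut points.
.axis_plan <- function(X, K) {
  if (X <= K) {
    return(data.frame(start = 0L, end = X, ilo = 0L, ihi = X))
  }
  starts <- seq(0L, X - K, by = K %/% 2L)
  if (tail(starts, 1L) + K < X) starts <- c(starts, X - K)
  ends <- starts + K
  nb <- length(starts)
  cuts <- integer(nb + 1L)
  cuts[1] <- 0L
  cuts[nb + 1L] <- X
  if (nb > 1L)
    for (i in seq_len(nb - 1L))
      cuts[i + 1L] <- (starts[i + 1L] + ends[i]) %/% 2L
  data.frame(start = starts, end = ends,
             ilo = cuts[seq_len(nb)], ihi = cuts[-1L])
}

#' Plan a tiled sweep over a volume
#'
#' @param shape Volume dimensions (X, Y, Z).
#' @param K Window edge length; even, >= 8, divisible by 4.
#' @return List of class `tiling_plan`: `K`, `shape`, and `tiles`, a list
#'   whose elements hold 0-based half-open ranges per axis: `window`
#'   (clamped to the volume), `padded` (window +/- K/4, possibly outside
#'   the volume), and `interior` (the region written to the output).
#' @export
plan_tiles <- function(shape, K = 128L) {
  K <- as.integer(K)
  if (K %% 2L != 0L) stop("K must be even", call. = FALSE)
  if (K %% 4L != 0L) stop("K must be divisible by 4", call. = FALSE)
  if (K < 8L) stop("K must be at least 8", call. = FALSE)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  ax <- lapply(shape, .axis_plan, K = K)
  pad <- K %/% 4L
  tiles <- list()
  for (i in seq_len(nrow(ax[[1]])))
    for (j in seq_len(nrow(ax[[2]])))
      for (k in seq_len(nrow(ax[[3]])))
        tiles[[length(tiles) + 1L]] <- list(
          window = rbind(x = c(ax[[1]]$start[i], ax[[1]]$end[i]),
                         y = c(ax[[2]]$start[j], ax[[2]]$end[j]),
                         z = c(ax[[3]]$start[k], ax[[3]]$end[k])),
          padded = rbind(x = c(ax[[1]]$start[i] - pad, ax[[1]]$end[i] + pad),
                         y = c(ax[[2]]$start[j] - pad, ax[[2]]$end[j] + pad),
                         z = c(ax[[3]]$start[k] - pad, ax[[3]]$end[k] + pad)),
          interior = rbind(x = c(ax[[1]]$ilo[i], ax[[1]]$ihi[i]),
                           y = c(ax[[2]]$ilo[j], ax[[2]]$ihi[j]),
                           z = c(ax[[3]]$ilo[k], ax[[3]]$ihi[k])))
  structure(list(K = K, shape = as.integer(shape), tiles = tiles),
            class = "tiling_plan")
}

#' @export
print.tiling_plan <- function(x, ...) {
  cat("Tiling plan: K =", x$K, "over", paste(x$shape, collapse = "x"),
      "volume;", length(x$tiles), "tiles\n")
  invisible(x)
}

# Reflected (mirror, edge-repeating) index lookup: 0-based i over axis
# length n -> 1-based array index.
.reflect_index <- function(i, n) {
  i <- ifelse(i < 0L, -1L - i, i)
  i <- ifelse(i >= n, 2L * n - 1L - i, i)
  i + 1L
}

# Extract the padded subvolume of `vol` for a tile (reflection padding).
.extract_padded <- function(vol, padded) {
  dm <- dim(vol)
  ix <- .reflect_index(padded[1, 1]:(padded[1, 2] - 1L), dm[1])
  iy <- .reflect_index(padded[2, 1]:(padded[2, 2] - 1L), dm[2])
  iz <- .reflect_index(padded[3, 1]:(padded[3, 2] - 1L), dm[3])
  vol[ix, iy, iz, drop = FALSE]
}

#' Tiled prediction over a large volume
#'
#' Runs `predictor` on every padded window of the plan and stitches only
#' the tile interiors into full-size outputs. Because interiors are
#' pairwise disjoint and cover the volume, any predictor whose output at a
#' voxel depends only on inputs within Chebyshev radius K/4 yields exactly
#' the untiled result. Instance splitting should run afterwards, once,
#' on the stitched mask and vector field.
#'
#' @param vol Intensity volume (X, Y, Z).
#' @param predictor Function taking a 3D array and returning
#'   `list(prob = <3D array>, vec = <4D array>)` of the same spatial shape.
#' @param K Window size (default 128).
#' @return List with `prob` (X, Y, Z) and `vec` (X, Y, Z, 3).
#' @export
predict_tiled <- function(vol, predictor, K = 128L) {
  plan <- plan_tiles(dim(vol), K)
  prob <- array(0, dim(vol))
  vec <- array(0, c(dim(vol), 3L))
  for (tile in plan$tiles) {
    sub <- .extract_padded(vol, tile$padded)
    out <- predictor(sub)
    if (!identical(dim(out$prob), dim(sub)) ||
        !identical(dim(out$vec)[1:3], dim(sub)))
      stop("predictor output shape does not match its input", call. = FALSE)
    int <- tile$interior
    # interior range relative to the padded window (1-based)
    rel <- lapply(1:3, function(a)
      (int[a, 1] - tile$padded[a, 1] + 1L):(int[a, 2] - tile$padded[a, 1]))
    gx <- (int[1, 1] + 1L):int[1, 2]
    gy <- (int[2, 1] + 1L):int[2, 2]
    gz <- (int[3, 1] + 1L):int[3, 2]
    prob[gx, gy, gz] <- out$prob[rel[[1]], rel[[2]], rel[[3]]]
    vec[gx, gy, gz, ] <- out$vec[rel[[1]], rel[[2]], rel[[3]], , drop = FALSE]
  }
  list(prob = prob, vec = vec)
}
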