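# Shared low-level array helpers: axis shifts, separable filtering,
# binary erosion. All operate on plain 3D arrays.

# Shift a 3D array by `o` along `axis`, with boundary handling:
#  - "zero": out-of-range positions become `fill`
#  - "clamp": edge replication (equals scipy-style reflect for |o| = 1)
# out[p] = arr[p - o] convention (contents move forward by o).
shift3 <- function(arr, o, axis, boundary = c("zero", "clamp"), fill = 0) {
  boundary <- match.arg(boundary)
  if (o == 0) return(arr)
  dm <- dim(arr)
  n <- dm[axis]
  src <- seq_len(n) - o
  if (boundary == "clamp") {
    src <- pmin(pmax(src, 1L), n)
    idx <- list(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]))
    idx[[axis]] <- src
    return(arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
  }
  out <- array(fill, dm)
  ok <- src >= 1L & src <= n
  if (!any(ok)) return(out)
  dst_idx <- list(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]))
  src_idx <- dst_idx
  dst_idx[[axis]] <- which(ok)
  src_idx[[axis]] <- src[ok]
  out[dst_idx[[1]], dst_idx[[2]], dst_idx[[3]]] <-
    arr[src_idx[[1]], src_idx[[2]], src_idx[[3]], drop = FALSE]
  out
}

# Correlate a 3D array with a 1D kernel along one axis.
conv_axis <- function(arr, kernel, axis, boundary = "clamp") {
  r <- (length(kernel) - 1L) %/% 2L
  out <- array(0, dim(arr))
  for (i in seq_along(kernel)) {
    o <- i - 1L - r
    if (kernel[i] == 0) next
    # correlation: out[p] = sum_k kernel[k] * arr[p + k] = shift by -o
    out <- out + kernel[i] * shift3(arr, -o, axis, boundary)
  }
  out
}

# Separable Gaussian blur with per-axis sigmas (0 skips the axis).
gaussian_blur3 <- function(arr, sigmas) {
  for (axis in 1:3) {
    s <- sigmas[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    arr <- conv_axis(arr, k, axis)
  }
  arr
}

# Offsets (integer matrix n x 3) of the TRUE cells of a structuring
# element relative to its center; SE must have odd dimensions.
se_offsets <- function(se) {
  dm <- dim(se)
  if (any(dm %% 2L == 0L))
    stop("structuring element must have odd dimensions", call. = FALSE)
  ctr <- (dm + 1L) %/% 2L
  w <- which(se != 0, arr.ind = TRUE)
  sweep(w, 2L, ctr, "-")
}

# Binary erosion of a logical 3D array by a structuring element
# (out-of-volume treated as background).
erode3 <- function(mask, se) {
  offs <- se_offsets(se)
  out <- array(TRUE, dim(mask))
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    sh <- mask
    for (axis in 1:3)
      if (o[axis] != 0) sh <- shift3(sh, -o[axis], axis, "zero", FALSE)
    out <- out & sh
  }
  out & mask
}

#' Structuring elements for conditional erosion
#'
#' `se_ellipsoid()` builds a discrete ellipsoid with the given semi-axes
#' (in voxels); `se_cross3()` is the 3x3x3 six-connected cross. These are
#' the default coarse and fine elements of [seg_params()].
#'
#' @param rx,ry,rz Semi-axes of the ellipsoid element (voxels).
#' @return Logical 3D array with odd dimensions, center `TRUE`.
#' @export
se_ellipsoid <- function(rx, ry, rz) {
  x <- (-rx):rx; y <- (-ry):ry; z <- (-rz):rz
  ax <- max(rx, 0.5); ay <- max(ry, 0.5); az <- max(rz, 0.5)
  g <- array(0, c(length(x), length(y), length(z)))
  xy <- outer(x^2 / ax^2, y^2 / ay^2, "+")
  for (k in seq_along(z)) g[, , k] <- xy + z[k]^2 / az^2
  g <= 1
}

#' @rdname se_ellipsoid
#' @export
se_cross3 <- function() {
  se <- array(FALSE, c(3, 3, 3))
  se[2, 2, 2] <- TRUE
  se[c(1, 3), 2, 2] <- TRUE
  se[2, c(1, 3), 2] <- TRUE
  se[2, 2, c(1, 3)] <- TRUE
  se
}
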