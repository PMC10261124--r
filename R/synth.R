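#' Configuration for synthetic label-volume generation
#'
#' Nuclei are modeled as randomly sized, oriented and placed ellipsoids;
#' placement is rejection-sampled against an overlap budget, and the final
#' label volume is elastically deformed by a smooth random displacement
#' field interpolated from a coarse Gaussian grid.
#'
#' @param shape Volume dimensions (X, Y, Z) in voxels.
#' @param n_nuclei Number of nuclei to attempt to place.
#' @param a_min,a_max Range of ellipsoid semi-axis lengths (voxels); each
#'   semi-axis is drawn independently and uniformly from this range.
#' @param t_ov Maximum number of voxels a candidate nucleus may share with
#'   previously placed nuclei.
#' @param d Edge length of the coarse deformation grid (>= 2).
#' @param sigma Standard deviation of the coarse displacement entries
#'   (voxels); 0 disables deformation.
#' @param max_attempts Rejection cap per nucleus before it is skipped.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(shape = c(128L, 128L, 128L), n_nuclei = 200L,
                         a_min = 6, a_max = 10, t_ov = 200L,
                         d = 5L, sigma = 2, max_attempts = 100L) {
  stopifnot(length(shape) == 3L, all(shape >= 1), n_nuclei >= 0,
            a_min >= 1, a_max >= a_min, t_ov >= 0, d >= 2, sigma >= 0)
  structure(list(shape = as.integer(shape), n_nuclei = as.integer(n_nuclei),
                 a_min = a_min, a_max = a_max, t_ov = as.integer(t_ov),
                 d = as.integer(d), sigma = sigma,
                 max_attempts = as.integer(max_attempts)),
            class = "synth_config")
}

#' Named generator presets
#'
#' Four presets (`"v1"`–`"v4"`) spanning the sparse-to-dense regimes the
#' generator is designed for (128^3 volumes), plus `"desk"`, a small
#' configuration suited to quick experiments and unit tests.
#'
#' @param name Preset name.
#' @return A `synth_config`.
#' @export
synth_preset <- function(name = c("v1", "v2", "v3", "v4", "desk")) {
  name <- match.arg(name)
  switch(name,
    v1 = synth_config(c(128L, 128L, 128L), 500L, 4, 8, 5L, 10L, 1),
    v2 = synth_config(c(128L, 128L, 128L), 70L, 10, 14, 10L, 4L, 1),
    v3 = synth_config(c(128L, 128L, 128L), 200L, 6, 10, 200L, 5L, 2),
    v4 = synth_config(c(128L, 128L, 128L), 560L, 8, 10, 100L, 4L, 4),
    desk = synth_config(c(64L, 64L, 64L), 15L, 4, 8, 10L, 5L, 2))
}

#' Draw the parameters of one random ellipsoid
#'
#' Semi-axes are independent uniform on `[a_min, a_max]`, rotation angles
#' independent uniform on `[0, 2*pi)`, and the center uniform over the
#' volume interior (0-based continuous coordinates). Uses the current RNG
#' state; seed with [set.seed()] for reproducibility.
#'
#' @param config A [synth_config()].
#' @param label Positive integer label to assign.
#' @return List with `a`, `theta`, `center`, `label`.
#' @export
sample_ellipsoid <- function(config, label = 1L) {
  list(a = runif(3, config$a_min, config$a_max),
       theta = runif(3, 0, 2 * pi),
       center = runif(3, 0, config$shape - 1),
       label = as.integer(label))
}

# Rotation matrices about the coordinate axes.
rot_x <- function(t) matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
rot_y <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
rot_z <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)

#' Rasterize an ellipsoid into voxel coordinates
#'
#' A voxel at 0-based coordinate `p` belongs to the ellipsoid when, after
#' rotating `p - center` into the ellipsoid's body frame (rotations about
#' X, then Y, then Z) and scaling by the reciprocal semi-axes, the squared
#' norm is strictly less than 1. Voxels outside the volume are clipped.
#'
#' @param p Ellipsoid parameters as from [sample_ellipsoid()].
#' @param shape Volume dimensions (X, Y, Z).
#' @return Integer matrix (n x 3) of 0-based voxel coordinates.
#' @export
rasterize_ellipsoid <- function(p, shape) {
  R <- rot_z(p$theta[3]) %*% rot_y(p$theta[2]) %*% rot_x(p$theta[1])
  # snap numerically-degraded right-angle rotations so boundary voxels do
  # not flip across the strict inequality
  R[abs(R) < 1e-12] <- 0
  R[abs(abs(R) - 1) < 1e-12] <- sign(R[abs(abs(R) - 1) < 1e-12])
  rmax <- max(p$a)
  lo <- pmax(ceiling(p$center - rmax), 0)
  hi <- pmin(floor(p$center + rmax), shape - 1)
  if (any(lo > hi)) return(matrix(integer(0), 0, 3))
  gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
  coords <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  q <- (coords - matrix(p$center, nrow(coords), 3, byrow = TRUE)) %*% t(R)
  q <- sweep(q, 2L, p$a, "/")
  inside <- rowSums(q^2) < 1
  coords[inside, , drop = FALSE]
}

# 0-based coordinates -> linear indices into an (X, Y, Z) array.
coords_to_index <- function(coords, shape) {
  1L + coords[, 1] + shape[1] * (coords[, 2] + shape[2] * coords[, 3])
}

#' Place overlap-constrained random nuclei into a label volume
#'
#' Ellipsoids are sampled and rasterized one at a time; a candidate is
#' accepted when at most `t_ov` of its voxels are already occupied by
#' earlier nuclei. Contested voxels keep the earlier label (first-come
#' priority). After `max_attempts` rejections a nucleus is skipped with a
#' warning. Accepted labels are consecutive `1..K`.
#'
#' @param config A [synth_config()].
#' @return Integer label array (X, Y, Z) with attributes `ellipsoids`
#'   (list of accepted parameters, pre-priority) and `skipped` (count).
#' @export
place_nuclei <- function(config) {
  shape <- config$shape
  vol <- array(0L, shape)
  accepted <- list()
  skipped <- 0L
  k <- 0L
  for (n in seq_len(config$n_nuclei)) {
    placed <- FALSE
    for (att in seq_len(config$max_attempts)) {
      p <- sample_ellipsoid(config, label = k + 1L)
      coords <- rasterize_ellipsoid(p, shape)
      if (nrow(coords) == 0L) next
      idx <- coords_to_index(coords, shape)
      if (sum(vol[idx] != 0L) <= config$t_ov) {
        free <- idx[vol[idx] == 0L]
        k <- k + 1L
        p$label <- k
        vol[free] <- k
        accepted[[k]] <- p
        placed <- TRUE
        break
      }
    }
    if (!placed) skipped <- skipped + 1L
  }
  if (skipped > 0L)
    warning(skipped, " nuclei skipped after ", config$max_attempts,
            " rejected attempts each", call. = FALSE)
  attr(vol, "ellipsoids") <- accepted
  attr(vol, "skipped") <- skipped
  vol
}

#' Random smooth displacement field for elastic deformation
#'
#' Draws a coarse `d x d x d x 3` field of i.i.d. N(0, sigma^2)
#' displacements anchored at equally spaced positions spanning the volume,
#' and interpolates each component to the full grid with natural cubic
#' splines (tensor-product, one axis at a time).
#'
#' @param shape Volume dimensions (X, Y, Z).
#' @param d Coarse grid edge length (>= 2).
#' @param sigma Displacement standard deviation in voxels.
#' @return List of class `deformation_field` with `coarse` (d,d,d,3) and
#'   `smooth` (X,Y,Z,3).
#' @export
make_deformation_field <- function(shape, d = 5L, sigma = 2) {
  stopifnot(d >= 2, sigma >= 0)
  coarse <- array(rnorm(d^3 * 3, 0, sigma), c(d, d, d, 3L))
  smooth <- array(0, c(shape, 3L))
  B <- lapply(1:3, function(axis) spline_basis(d, shape[axis]))
  for (cc in 1:3) {
    f <- coarse[, , , cc]
    f <- mat_along_axis(f, B[[1]], 1L)
    f <- mat_along_axis(f, B[[2]], 2L)
    f <- mat_along_axis(f, B[[3]], 3L)
    smooth[, , , cc] <- f
  }
  structure(list(coarse = coarse, smooth = smooth),
            class = "deformation_field")
}

# Cardinal natural-cubic-spline interpolation matrix from d anchors
# (equally spaced on [0, n-1]) to the n-point full grid. Interpolation is
# linear in the anchor values, so the map is a fixed n x d matrix.
spline_basis <- function(d, n) {
  anchors <- seq(0, n - 1, length.out = d)
  at <- seq_len(n) - 1
  B <- matrix(0, n, d)
  for (j in seq_len(d)) {
    e <- numeric(d); e[j] <- 1
    B[, j] <- splinefun(anchors, e, method = "natural")(at)
  }
  B
}

# Apply matrix B (n_out x n_in) along one axis of a 3D array.
mat_along_axis <- function(arr, B, axis) {
  dm <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- B %*% matrix(a, dm[axis])
  out <- array(m, c(nrow(B), dm[perm[2]], dm[perm[3]]))
  aperm(out, order(perm))
}

#' Warp a label volume by a displacement field
#'
#' Backward warp with nearest-neighbor sampling: the output voxel at `p`
#' takes the input label at `p - smooth(p)` (rounded); samples falling
#' outside the volume map to background. No new labels can appear.
#'
#' @param labels Integer label array (X, Y, Z).
#' @param field A `deformation_field` whose `smooth` shape matches.
#' @return Deformed label array.
#' @export
apply_deformation <- function(labels, field) {
  assert_labels(labels)
  dm <- dim(labels)
  sm <- field$smooth
  if (!identical(dim(sm)[1:3], dm) || dim(sm)[4] != 3L)
    stop("displacement field shape does not match the label volume",
         call. = FALSE)
  n <- prod(dm)
  cx <- rep.int(seq_len(dm[1]), dm[2] * dm[3])
  cy <- rep.int(rep(seq_len(dm[2]), each = dm[1]), dm[3])
  cz <- rep(seq_len(dm[3]), each = dm[1] * dm[2])
  sx <- round(cx - sm[seq_len(n)])
  sy <- round(cy - sm[n + seq_len(n)])
  sz <- round(cz - sm[2 * n + seq_len(n)])
  ok <- sx >= 1 & sx <= dm[1] & sy >= 1 & sy <= dm[2] & sz >= 1 & sz <= dm[3]
  out <- array(0L, dm)
  src <- sx[ok] + dm[1] * (sy[ok] - 1) + dm[1] * dm[2] * (sz[ok] - 1)
  out[which(ok)] <- labels[src]
  out
}

#' Generate a synthetic instance label volume
#'
#' Convenience composition: [place_nuclei()] followed by elastic
#' deformation with [make_deformation_field()] / [apply_deformation()]
#' (skipped when `config$sigma == 0` or `deform = FALSE`).
#'
#' @param config A [synth_config()].
#' @param seed Optional integer seed applied before any sampling.
#' @param deform Apply the elastic deformation step.
#' @return Integer label array (X, Y, Z).
#' @export
synth_labels <- function(config, seed = NULL, deform = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  vol <- place_nuclei(config)
  ell <- attr(vol, "ellipsoids")
  if (deform && config$sigma > 0) {
    field <- make_deformation_field(config$shape, config$d, config$sigma)
    vol <- apply_deformation(vol, field)
    attr(vol, "ellipsoids") <- ell
  }
  vol
}
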