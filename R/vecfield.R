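#' Instance centroids of a label volume
#'
#' The centroid of label `k` is the unweighted arithmetic mean of the
#' 0-based coordinates of all voxels carrying `k`; no rounding is applied.
#'
#' @param labels Integer label array (X, Y, Z), 0 = background.
#' @return Numeric matrix (K x 3), columns (x, y, z), rownames the labels,
#'   ordered by label. Zero rows for an empty volume.
#' @export
compute_centroids <- function(labels) {
  assert_labels(labels)
  idx <- which(labels != 0L)
  if (length(idx) == 0L)
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z"))))
  dm <- dim(labels)
  co <- arrayInd(idx, dm) - 1  # 0-based
  lab <- as.vector(labels[idx])
  sums <- rowsum(co, lab)
  cnt <- as.vector(rowsum(rep(1, length(lab)), lab))
  ctr <- sums / cnt
  colnames(ctr) <- c("x", "y", "z")
  ctr
}

#' Ground-truth centroid-offset vector field of a label volume
#'
#' For every voxel owned by nucleus `k`, the field holds the 3D offset
#' from the voxel to the centroid of `k` (in voxels); background voxels
#' hold the exact zero vector. The owning label, not metric nearness,
#' determines the target centroid.
#'
#' @param labels Integer label array (X, Y, Z).
#' @return Numeric (X, Y, Z, 3) array, component order (x, y, z).
#' @export
generate_vector_field <- function(labels) {
  assert_labels(labels)
  dm <- dim(labels)
  vf <- array(0, c(dm, 3L))
  idx <- which(labels != 0L)
  if (length(idx) == 0L) return(vf)
  ctr <- compute_centroids(labels)
  co <- arrayInd(idx, dm) - 1
  lab <- as.character(labels[idx])
  n <- prod(dm)
  for (cc in 1:3)
    vf[idx + (cc - 1L) * n] <- ctr[lab, cc] - co[, cc]
  vf
}
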