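# Shared independent oracles for the test suite. These deliberately use
# naive/brute-force implementations distinct from the package internals.

# 3x3x3 mean filter with reflected (edge-repeating) boundary, computed by
# explicit triple loop over kernel offsets with clamped indexing.
brute_mean_filter <- function(vol) {
  dm <- dim(vol)
  out <- array(0, dm)
  for (ox in -1:1) for (oy in -1:1) for (oz in -1:1) {
    ix <- pmin(pmax(seq_len(dm[1]) + ox, 1L), dm[1])
    iy <- pmin(pmax(seq_len(dm[2]) + oy, 1L), dm[2])
    iz <- pmin(pmax(seq_len(dm[3]) + oz, 1L), dm[3])
    out <- out + vol[ix, iy, iz]
  }
  out / 27
}

# brute-force one-to-one matching maximizing (matches, total IoU) by full
# permutation enumeration over the smaller side (<= 6 instances)
brute_best_matching <- function(iou, t) {
  ng <- nrow(iou); np <- ncol(iou)
  if (ng == 0 || np == 0) return(0L)
  best <- 0L
  gt_idx <- seq_len(ng)
  # enumerate all injective maps from gt subset to preds
  perms <- function(pool, k) {
    if (k == 0) return(list(integer(0)))
    out <- list()
    for (i in seq_along(pool))
      for (rest in perms(pool[-i], k - 1))
        out[[length(out) + 1]] <- c(pool[i], rest)
    out
  }
  for (k in seq_len(min(ng, np))) {
    subsets <- utils::combn(ng, k, simplify = FALSE)
    for (gs in subsets)
      for (pm in perms(seq_len(np), k)) {
        if (all(iou[cbind(gs, pm)] >= t)) best <- max(best, k)
      }
  }
  best
}

# brute-force voxel rasterization oracle: test every voxel of the volume
# against the rotated ellipsoid inequality
brute_rasterize_count <- function(a, theta, center, shape) {
  Rx <- matrix(c(1, 0, 0, 0, cos(theta[1]), sin(theta[1]),
                 0, -sin(theta[1]), cos(theta[1])), 3, 3)
  Ry <- matrix(c(cos(theta[2]), 0, -sin(theta[2]), 0, 1, 0,
                 sin(theta[2]), 0, cos(theta[2])), 3, 3)
  Rz <- matrix(c(cos(theta[3]), sin(theta[3]), 0,
                 -sin(theta[3]), cos(theta[3]), 0, 0, 0, 1), 3, 3)
  R <- Rz %*% Ry %*% Rx
  cnt <- 0L
  for (x in 0:(shape[1] - 1)) for (y in 0:(shape[2] - 1))
    for (z in 0:(shape[3] - 1)) {
      q <- R %*% (c(x, y, z) - center)
      if (sum((q / a)^2) < 1) cnt <- cnt + 1L
    }
  cnt
}

# tiny deterministic two-cube volume pair used in the metric worked example
shifted_cube_pair <- function() {
  gt <- array(0L, c(6, 6, 6))
  gt[2:3, 2:3, 2:3] <- 1L
  pred <- array(0L, c(6, 6, 6))
  pred[3:4, 2:3, 2:3] <- 1L
  list(gt = gt, pred = pred)
}

# random small label volume: a few non-touching boxes
random_box_labels <- function(shape, n, seed) {
  set.seed(seed)
  vol <- array(0L, shape)
  k <- 0L
  for (i in seq_len(n)) {
    sz <- sample(2:4, 3, replace = TRUE)
    for (att in 1:50) {
      lo <- sapply(seq_len(3), function(a) sample(shape[a] - sz[a], 1))
      sl <- list(lo[1]:(lo[1] + sz[1] - 1), lo[2]:(lo[2] + sz[2] - 1),
                 lo[3]:(lo[3] + sz[3] - 1))
      if (all(vol[sl[[1]], sl[[2]], sl[[3]]] == 0L)) {
        k <- k + 1L
        vol[sl[[1]], sl[[2]], sl[[3]]] <- k
        break
      }
    }
  }
  vol
}
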