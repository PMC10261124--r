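#' Parameters for vector-field instance splitting
#'
#' @param T_m Gradient threshold: foreground voxels whose gradient-map
#'   value is >= `T_m` are carved out of the blob map. The gradient map
#'   uses unnormalized 3D Sobel kernels (responses scale ~16x the raw
#'   per-voxel component jump), so `T_m` lives on that scale.
#' @param t_c,t_f Coarse and fine component-size thresholds (voxels):
#'   each connected component is iteratively eroded with `B_c` while its
#'   size is >= `t_c`, then with `B_f` while >= `t_f`.
#' @param B_c,B_f Binary 3D structuring elements (odd dims, center TRUE).
#'   Defaults: 5x5x3 discrete ellipsoid (coarser axial sampling) and the
#'   3x3x3 six-connected cross.
#' @param min_size Instances smaller than this many voxels are removed at
#'   the end (default 20).
#' @param abs_gradient Use the absolute instead of the signed Sobel
#'   responses in the gradient map.
#' @param elevation Watershed elevation surface: `"distance"` (negative
#'   Euclidean distance transform of the mask) or `"blend"` (distance
#'   blended with inverted smoothed intensity at weight `blend_weight`).
#' @param blend_weight Weight of the intensity term for `"blend"`.
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(T_m = 64, t_c = 400L, t_f = 150L,
                       B_c = se_ellipsoid(2, 2, 1), B_f = se_cross3(),
                       min_size = 20L, abs_gradient = FALSE,
                       elevation = c("distance", "blend"),
                       blend_weight = 0) {
  elevation <- match.arg(elevation)
  stopifnot(t_c >= t_f, t_f >= 1, min_size >= 0,
            blend_weight >= 0, blend_weight <= 1)
  ctr <- function(se) se[matrix((dim(se) + 1L) %/% 2L, 1)]
  if (!ctr(B_c) || !ctr(B_f))
    stop("structuring elements must contain their center", call. = FALSE)
  structure(list(T_m = T_m, t_c = as.integer(t_c), t_f = as.integer(t_f),
                 B_c = B_c, B_f = B_f, min_size = as.integer(min_size),
                 abs_gradient = abs_gradient, elevation = elevation,
                 blend_weight = blend_weight),
            class = "seg_params")
}

#' Instance-splitting presets
#'
#' Named presets carrying the gradient and erosion thresholds used for the
#' five benchmark volume types under the two training regimes
#' (`slim-v1..slim-v5`, `synth-v1..synth-v4`), plus `"desk"`, calibrated
#' for the synthetic desk-scale fixtures this package generates (nucleus
#' semi-axes around 4-8 voxels, ground-truth-quality vector fields).
#'
#' @param name Preset name.
#' @return A [seg_params()].
#' @export
seg_preset <- function(name = "desk") {
  tab <- list(
    `slim-v1`  = c(5, 700, 200),  `slim-v2`  = c(5, 3000, 500),
    `slim-v3`  = c(1, 2000, 700), `slim-v4`  = c(1, 2000, 300),
    `slim-v5`  = c(0, 2000, 200), `synth-v1` = c(0, 2000, 200),
    `synth-v2` = c(0, 2000, 200), `synth-v3` = c(4, 2000, 500),
    `synth-v4` = c(0, 2000, 200),
    desk       = c(64, 400, 150))
  if (!name %in% names(tab)) stop("unknown preset: ", name, call. = FALSE)
  v <- tab[[name]]
  seg_params(T_m = v[1], t_c = v[2], t_f = v[3])
}

#' Gradient map of a vector field
#'
#' Each component is differentiated along its own axis with an
#' unnormalized 3D Sobel kernel (derivative stencil `[-1, 0, 1]` on its
#' own axis, smoothing `[1, 2, 1]` on the other two; reflected boundary);
#' the map is the elementwise signed maximum of the three responses.
#' Vectors on the two sides of a boundary between touching nuclei point to
#' different centroids, so the own-axis derivative jumps positive there,
#' while converging vectors make nucleus interiors negative.
#'
#' @param vf Vector field (X, Y, Z, 3).
#' @param abs_gradient Take absolute responses before the maximum.
#' @return Numeric (X, Y, Z) gradient map.
#' @export
gradient_map <- function(vf, abs_gradient = FALSE) {
  assert_vecfield(vf)
  deriv <- c(-1, 0, 1)
  smooth <- c(1, 2, 1)
  g <- NULL
  for (cc in 1:3) {
    r <- vf[, , , cc]
    for (axis in 1:3)
      r <- conv_axis(r, if (axis == cc) deriv else smooth, axis)
    if (abs_gradient) r <- abs(r)
    g <- if (is.null(g)) r else pmax(g, r)
  }
  g
}

#' Blob map: carve high-gradient boundary voxels out of the mask
#'
#' `relu(mask - (G >= T_m))`: foreground voxels whose gradient-map value
#' reaches the threshold are removed, disconnecting touching nuclei.
#'
#' @param mask Logical or 0/1 array (X, Y, Z).
#' @param G Gradient map, same shape.
#' @param T_m Threshold.
#' @return Logical array.
#' @export
blob_map <- function(mask, G, T_m) {
  if (!identical(dim(mask), dim(G)))
    stop("shape mismatch between mask and gradient map", call. = FALSE)
  (mask > 0) & (G < T_m)
}

#' Conditional erosion: shrink blobs into watershed markers
#'
#' Connected components (26-connectivity) of the blob map are iteratively
#' eroded — first with the coarse element while their size is >= `t_c`,
#' then with the fine element while >= `t_f` — re-splitting into
#' components after every erosion pass and processing each piece
#' independently. A component that an erosion would annihilate keeps its
#' last nonempty state. Surviving components are relabeled `1..M`.
#'
#' @param blob Logical/0-1 array (X, Y, Z).
#' @param p A [seg_params()].
#' @return Integer marker array (X, Y, Z).
#' @export
conditional_erosion <- function(blob, p = seg_params()) {
  dm <- dim(blob)
  markers <- array(0L, dm)
  next_label <- 0L
  # queue entries: list(indices (linear), phase 1 = coarse, 2 = fine)
  init <- cc_label(blob)
  queue <- lapply(seq_len(max(init, 0L)), function(k)
    list(idx = which(init == k), phase = 1L))
  se <- list(p$B_c, p$B_f)
  thr <- c(p$t_c, p$t_f)
  while (length(queue) > 0L) {
    item <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    ph <- item$phase
    if (ph > 2L || length(item$idx) < thr[ph]) {
      if (ph >= 2L || length(item$idx) < thr[2L]) {
        next_label <- next_label + 1L
        markers[item$idx] <- next_label
      } else {
        queue[[length(queue) + 1L]] <- list(idx = item$idx, phase = 2L)
      }
      next
    }
    piece <- component_box(item$idx, dm, se[[ph]])
    er <- erode3(piece$arr, se[[ph]])
    if (!any(er)) {  # vanish protection: keep last nonempty state
      next_label <- next_label + 1L
      markers[item$idx] <- next_label
      next
    }
    lab <- cc_label(er)
    for (k in seq_len(max(lab))) {
      sub <- which(lab == k)
      queue[[length(queue) + 1L]] <-
        list(idx = piece$to_global(sub), phase = ph)
    }
  }
  markers
}

# Extract the bounding box of a voxel index set (with a 1-voxel margin)
# as a logical array plus a mapping back to global linear indices.
component_box <- function(idx, dm, se) {
  co <- arrayInd(idx, dm)
  lo <- pmax(apply(co, 2, min) - 1L, 1L)
  hi <- pmin(apply(co, 2, max) + 1L, dm)
  sz <- hi - lo + 1L
  arr <- array(FALSE, sz)
  loc <- sweep(co, 2, lo - 1L, "-")
  arr[loc] <- TRUE
  list(arr = arr, to_global = function(sub_idx) {
    sco <- arrayInd(sub_idx, sz)
    g <- sweep(sco, 2, lo - 1L, "+")
    g[, 1] + dm[1] * (g[, 2] - 1L) + dm[1] * dm[2] * (g[, 3] - 1L)
  })
}

# 26- or 6-connected component labeling (compiled).
cc_label <- function(mask, connectivity = 26L) {
  dm <- dim(mask)
  lab <- .cc_label_cpp(as.integer(mask != 0), as.integer(dm),
                       as.integer(connectivity))
  array(lab, dm)
}

# Squared Euclidean distance transform of a binary mask (compiled).
edt_squared <- function(mask) {
  dm <- dim(mask)
  array(.edt_sq_cpp(as.integer(mask != 0), as.integer(dm)), dm)
}

#' Marker-controlled watershed restricted to a mask
#'
#' Floods an elevation surface (by default the negative Euclidean distance
#' transform of the mask, optionally blended with inverted smoothed
#' intensity) from the labeled markers; every reachable foreground voxel
#' receives exactly one label. Foreground components containing no marker
#' are rescued as single new instances. Markers outside the mask are
#' clipped with a warning.
#'
#' @param markers Integer marker array (X, Y, Z).
#' @param mask Logical/0-1 foreground mask, same shape.
#' @param intensity Optional intensity volume for the blended elevation.
#' @param p A [seg_params()].
#' @return Integer label array.
#' @export
watershed_split <- function(markers, mask, intensity = NULL,
                            p = seg_params()) {
  dm <- dim(mask)
  fg <- mask > 0
  if (!any(fg)) return(array(0L, dm))
  if (any(markers[!fg] != 0L)) {
    warning("markers outside the mask were clipped", call. = FALSE)
    markers[!fg] <- 0L
  }
  elev <- -sqrt(edt_squared(fg))
  if (p$elevation == "blend" && !is.null(intensity) && p$blend_weight > 0) {
    sm <- gaussian_blur3(intensity / max(intensity, 1), c(1, 1, 1))
    rng <- range(elev)
    elev_n <- if (diff(rng) > 0) (elev - rng[1]) / diff(rng) else elev * 0
    elev <- (1 - p$blend_weight) * elev_n + p$blend_weight * (-sm)
  }
  seg <- array(.watershed_cpp(as.numeric(elev), as.integer(markers),
                              as.integer(fg), as.integer(dm)), dm)
  orphan <- fg & seg == 0L
  if (any(orphan)) {
    extra <- cc_label(orphan)
    base <- max(seg)
    seg[orphan] <- extra[orphan] + base
  }
  seg
}

#' Remove small instances and compact labels
#'
#' @param seg Integer label array.
#' @param min_size Instances with fewer voxels than this are set to
#'   background; survivors are relabeled `1..K`. Idempotent.
#' @return Integer label array.
#' @export
remove_small <- function(seg, min_size = 20L) {
  mx <- max(seg)
  if (mx == 0L) return(seg)
  cnt <- tabulate(seg[seg != 0L], nbins = mx)
  keep <- which(cnt >= min_size)
  lut <- integer(mx)
  lut[keep] <- seq_along(keep)
  out <- array(0L, dim(seg))
  fg <- seg != 0L
  out[fg] <- lut[seg[fg]]
  out
}

#' Split an instance segmentation out of a mask and vector field
#'
#' Full composition of the instance-splitting stage: gradient map ->
#' blob map -> conditional erosion -> marker-controlled watershed ->
#' small-object removal. The mask may be given as probabilities, which are
#' binarized at 0.5.
#'
#' @param mask Foreground mask (logical/0-1) or probability array.
#' @param vf Vector field (X, Y, Z, 3) — the estimate from the network, or
#'   the ground-truth field in oracle mode.
#' @param p A [seg_params()].
#' @param intensity Optional intensity volume (blended elevation only).
#' @return Integer instance label array.
#' @export
segment_instances <- function(mask, vf, p = seg_params(), intensity = NULL) {
  if (!identical(dim(mask), dim(vf)[1:3]))
    stop("mask and vector field shapes differ", call. = FALSE)
  fg <- mask >= 0.5
  if (!any(fg)) return(array(0L, dim(fg)))
  G <- gradient_map(vf, abs_gradient = p$abs_gradient)
  blob <- blob_map(fg, G, p$T_m)
  markers <- conditional_erosion(blob, p)
  seg <- watershed_split(markers, fg, intensity, p)
  remove_small(seg, p$min_size)
}
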