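# Contract checks for the three volume kinds. Kept as plain functions
# (volumes are base arrays); each returns its input invisibly so checks
# can be chained at module boundaries.

assert_intensity <- function(vol, what = "intensity volume") {
  if (!is.array(vol) || length(dim(vol)) != 3L)
    stop(what, " must be a 3D array (X, Y, Z)", call. = FALSE)
  if (any(dim(vol) < 1L)) stop(what, " has an empty axis", call. = FALSE)
  if (anyNA(vol)) stop(what, " contains NA", call. = FALSE)
  if (min(vol) < 0) stop(what, " contains negative intensities", call. = FALSE)
  invisible(vol)
}

assert_labels <- function(vol, what = "label volume") {
  if (!is.array(vol) || length(dim(vol)) != 3L)
    stop(what, " must be a 3D array (X, Y, Z)", call. = FALSE)
  if (anyNA(vol)) stop(what, " contains NA", call. = FALSE)
  v <- as.vector(vol)
  if (any(v != round(v)))
    stop(what, " contains non-integer values", call. = FALSE)
  if (min(v) < 0) stop(what, " contains negative labels", call. = FALSE)
  invisible(vol)
}

assert_vecfield <- function(vf, what = "vector field") {
  if (!is.array(vf) || length(dim(vf)) != 4L || dim(vf)[4] != 3L)
    stop(what, " must be a 4D array (X, Y, Z, 3)", call. = FALSE)
  if (anyNA(vf)) stop(what, " contains NA", call. = FALSE)
  invisible(vf)
}

# shape helper
vol_dim <- function(vol) dim(vol)[1:3]
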