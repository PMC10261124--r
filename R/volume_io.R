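#' Read a 3D volume (or vector field) from a multi-page TIFF
#'
#' Pages map to Z slices; within a page, rows are Y and columns are X, so
#' the returned array has axes (X, Y, Z). Integer-format pages are read
#' losslessly at their stored bit depth. See [write_volume()] for how
#' label volumes beyond 16-bit range and vector fields are stored.
#'
#' @param path Path to an existing TIFF file.
#' @param kind One of `"intensity"`, `"label"`, `"vector"`. Label reads
#'   reject non-integer data; intensity reads reject negative data; vector
#'   reads expect 3 samples per voxel.
#' @return A 3D array (X, Y, Z) for `"intensity"`/`"label"`, or a 4D array
#'   (X, Y, Z, 3) for `"vector"`.
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, kind = c("intensity", "label", "vector")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  if (kind == "vector") {
    # normalized read: values come back in [0, 1] regardless of depth
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    nd <- length(dim(pages[[1]]))
    if (nd != 3L || dim(pages[[1]])[3] != 3L)
      stop("vector-field TIFF must carry 3 samples per voxel", call. = FALSE)
    Ydim <- dim(pages[[1]])[1]; Xdim <- dim(pages[[1]])[2]
    Zdim <- length(pages)
    vf <- array(0, c(Xdim, Ydim, Zdim, 3L))
    for (z in seq_len(Zdim)) {
      pg <- pages[[z]]
      for (cc in 1:3) vf[, , z, cc] <- t(pg[, , cc])
    }
    sc <- .vec_tiff_scale(c(Xdim, Ydim, Zdim))
    return((vf - 0.5) * sc)
  }

  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) != 2L)
    stop("non-scalar samples: expected one grayscale sample per voxel",
         call. = FALSE)
  bits <- attr(pages[[1]], "info")$bits.per.sample
  Ydim <- dim(pages[[1]])[1]; Xdim <- dim(pages[[1]])[2]
  Zdim <- length(pages)
  vol <- array(0, c(Xdim, Ydim, Zdim))
  for (z in seq_len(Zdim)) vol[, , z] <- t(pages[[z]])

  if (kind == "label") {
    assert_labels(vol)
    if (max(vol) <= .Machine$integer.max) storage.mode(vol) <- "integer"
    vol
  } else {
    # [0,1] intensity volumes quantized to 32-bit come back as raw counts;
    # undo the quantization (integer-depth files are left untouched)
    if (identical(bits, 32L) && max(vol) > 1 && all(vol == round(vol)))
      vol <- vol / (2^32 - 1)
    assert_intensity(vol)
    vol
  }
}

# Fixed self-describing scale for TIFF vector fields: offsets are bounded
# by the volume diagonal, so component c is stored as 0.5 + c / scale with
# scale = 4 * ceil(diagonal), recoverable from the page dimensions.
.vec_tiff_scale <- function(shape) 4 * ceiling(sqrt(sum(shape^2)))

#' Write a volume or vector field as a multi-page TIFF
#'
#' Integer volumes are stored losslessly at the smallest sufficient
#' unsigned depth: 8-bit, 16-bit, or 32-bit (for label volumes whose
#' maximum exceeds 65535); the round trip through [read_volume()] is
#' bit-exact, and labels at or beyond 2^32 raise an overflow error.
#' Non-integer intensity volumes must lie in \[0, 1\] and are quantized to
#' 32-bit. Vector fields are written as 3-sample pages with components
#' affinely mapped into \[0, 1\] by a scale derived from the volume
#' diagonal (offsets are bounded by the diagonal), so the round trip is
#' exact to within single-precision resolution.
#'
#' @param vol 3D array (intensity or label) or 4D (X, Y, Z, 3) vector field.
#' @param path Output path; the parent directory must exist.
#' @param kind Storage interpretation; inferred from the array when omitted
#'   (4D -> vector, 3D -> intensity). Pass `kind = "label"` to apply the
#'   label dtype rules.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path,
                         kind = c("auto", "intensity", "label", "vector")) {
  kind <- match.arg(kind)
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path), call. = FALSE)
  if (kind == "auto")
    kind <- if (length(dim(vol)) == 4L) "vector" else "intensity"

  if (kind == "vector") {
    assert_vecfield(vol)
    dm <- dim(vol)
    sc <- .vec_tiff_scale(dm[1:3])
    if (max(abs(vol)) > sc / 2)
      stop("vector components exceed the storable range", call. = FALSE)
    pages <- lapply(seq_len(dm[3]), function(z) {
      pg <- array(0, c(dm[2], dm[1], 3L))
      for (cc in 1:3) pg[, , cc] <- t(vol[, , z, cc] / sc + 0.5)
      pg
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    return(invisible(path))
  }

  v <- as.vector(vol)
  mx <- max(v)
  integerish <- all(v == round(v))
  if (kind == "label") {
    assert_labels(vol)
    if (mx >= 2^31)
      stop("label overflow: labels must fit a 32-bit signed integer",
           call. = FALSE)
  } else {
    assert_intensity(vol)
    if (!integerish) {
      if (mx > 1)
        stop("non-integer intensity volumes must lie in [0, 1] for TIFF ",
             "storage", call. = FALSE)
      pages <- lapply(seq_len(dim(vol)[3]), function(z) t(vol[, , z]))
      tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
      return(invisible(path))
    }
    if (mx >= 2^32)
      stop("integer intensities must fit 32-bit unsigned", call. = FALSE)
  }

  bits <- if (mx <= 255) 8L else if (mx <= 65535) 16L else 32L
  denom <- c(`8` = 255, `16` = 65535, `32` = 2^32 - 1)[[as.character(bits)]]
  pages <- lapply(seq_len(dim(vol)[3]), function(z) t(vol[, , z]) / denom)
  tiff::writeTIFF(pages, path, bits.per.sample = bits, reduce = FALSE)
  invisible(path)
}
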