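#' Configuration for the classical intensity renderer
#'
#' Turns a label volume into a plausible fluorescence-like intensity
#' volume: per-instance brightness jitter, anisotropic Gaussian blur
#' (axial sigma larger than lateral, mimicking the elongated point-spread
#' function of confocal stacks), background offset, sensor noise, and
#' quantization. All intensity-like parameters are fractions of the output
#' dynamic range.
#'
#' @param psf_sigma_xy,psf_sigma_z Gaussian blur sigmas (voxels), lateral
#'   and axial.
#' @param intensity_mean Mean nucleus brightness (fraction of range).
#' @param intensity_jitter Per-instance brightness jitter: each instance is
#'   painted at `intensity_mean * (1 + u)`, `u ~ U(-jitter, jitter)`.
#' @param background Background level (fraction of range); must be below
#'   `intensity_mean`.
#' @param noise `"gaussian"` (additive, sd `noise_sd`) or
#'   `"poisson-gaussian"` (shot noise at `poisson_scale` photons per unit
#'   intensity plus additive read noise of sd `noise_sd`).
#' @param noise_sd Additive noise sd (fraction of range).
#' @param poisson_scale Photons per unit intensity for shot noise.
#' @param bit_depth 8 or 16.
#' @return A list of class `render_config`.
#' @export
render_config <- function(psf_sigma_xy = 1, psf_sigma_z = 2,
                          intensity_mean = 0.6, intensity_jitter = 0.15,
                          background = 0.1,
                          noise = c("gaussian", "poisson-gaussian"),
                          noise_sd = 0.03, poisson_scale = 400,
                          bit_depth = 8L) {
  noise <- match.arg(noise)
  stopifnot(psf_sigma_xy >= 0, psf_sigma_z >= 0,
            intensity_jitter >= 0, intensity_jitter < 1,
            background < intensity_mean, bit_depth %in% c(8L, 16L))
  structure(list(psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
                 intensity_mean = intensity_mean,
                 intensity_jitter = intensity_jitter,
                 background = background, noise = noise,
                 noise_sd = noise_sd, poisson_scale = poisson_scale,
                 bit_depth = as.integer(bit_depth)),
            class = "render_config")
}

#' Render a label volume into an intensity volume
#'
#' @param labels Integer label array (X, Y, Z).
#' @param cfg A [render_config()].
#' @return Integer intensity array (X, Y, Z) quantized to the configured
#'   bit depth. Uses the current RNG state.
#' @export
render_volume <- function(labels, cfg = render_config()) {
  assert_labels(labels)
  labs <- sort(unique(as.vector(labels[labels != 0L])))
  img <- array(0, dim(labels))
  if (length(labs) > 0L) {
    gain <- cfg$intensity_mean *
      (1 + runif(length(labs), -cfg$intensity_jitter, cfg$intensity_jitter))
    lut <- numeric(max(labs))
    lut[labs] <- gain
    fg <- labels != 0L
    img[fg] <- lut[labels[fg]]
  }
  img <- gaussian_blur3(img, c(cfg$psf_sigma_xy, cfg$psf_sigma_xy,
                               cfg$psf_sigma_z))
  img <- img + cfg$background
  if (cfg$noise == "gaussian") {
    if (cfg$noise_sd > 0)
      img <- img + array(rnorm(length(img), 0, cfg$noise_sd), dim(img))
  } else {
    img <- array(rpois(length(img), pmax(img, 0) * cfg$poisson_scale),
                 dim(img)) / cfg$poisson_scale
    if (cfg$noise_sd > 0)
      img <- img + array(rnorm(length(img), 0, cfg$noise_sd), dim(img))
  }
  mx <- 2^cfg$bit_depth - 1
  out <- round(pmin(pmax(img, 0), 1) * mx)
  array(as.integer(out), dim(labels))
}
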