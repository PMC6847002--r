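#' Acquisition parameters for simulated and real image data
#'
#' Bundles the physical scales of an acquisition: voxel dimensions, frame
#' interval, image geometry, a Gaussian approximation of the point-spread
#' function, and the camera noise model (photon shot noise plus additive
#' Gaussian read noise, quantized to the camera bit depth).
#'
#' @param pixel_size Lateral pixel size in micrometres per pixel. The default
#'   0.16 um is a typical 100x objective / EMCCD scale; all dynamics
#'   quantities are computed in micrometres, so any positive value is valid.
#' @param z_step Axial spacing between consecutive z-slices in micrometres
#'   (default 0.25).
#' @param frame_interval Time between consecutive movie frames in seconds
#'   (default 0.1, i.e. 10 frames per second).
#' @param image_shape Integer vector `c(slices, rows, cols)` for z-stacks or
#'   `c(frames, rows, cols)` for movies.
#' @param psf_sigma_lateral Lateral standard deviation of the Gaussian PSF
#'   model, in pixels. The default 1 px (0.16 um) is the diffraction-limited
#'   width of a widefield spot at this pixel scale
#'   (`sigma ~ 0.21 * lambda / NA ~ 0.1 um` for visible emission at NA 1.4,
#'   broadened slightly by aberration and pixelation).
#' @param psf_sigma_axial Axial standard deviation of the Gaussian PSF model,
#'   in slices (default 1 slice = 0.25 um, matching the widefield axial
#'   extent).
#' @param background_level Mean background photon count per voxel.
#' @param read_noise_sd Standard deviation of the additive Gaussian read
#'   noise, in photons.
#' @param bit_depth Camera bit depth; intensities are clamped to
#'   `[0, 2^bit_depth - 1]` and rounded.
#'
#' @return An object of class `acquisition_params` (a validated list).
#' @examples
#' p <- acquisition_params(image_shape = c(12, 48, 48))
#' p$z_step
#' @export
acquisition_params <- function(pixel_size = 0.16,
                               z_step = 0.25,
                               frame_interval = 0.1,
                               image_shape = c(12L, 64L, 64L),
                               psf_sigma_lateral = 1,
                               psf_sigma_axial = 1,
                               background_level = 100,
                               read_noise_sd = 2,
                               bit_depth = 16L) {
  stopifnot(
    is.numeric(pixel_size), length(pixel_size) == 1, pixel_size > 0,
    is.numeric(z_step), length(z_step) == 1, z_step > 0,
    is.numeric(frame_interval), length(frame_interval) == 1, frame_interval > 0,
    is.numeric(image_shape), length(image_shape) == 3, all(image_shape >= 1),
    psf_sigma_lateral > 0, psf_sigma_axial > 0,
    background_level >= 0, read_noise_sd >= 0,
    bit_depth >= 1, bit_depth <= 32
  )
  structure(
    list(
      pixel_size = pixel_size,
      z_step = z_step,
      frame_interval = frame_interval,
      image_shape = as.integer(image_shape),
      psf_sigma_lateral = psf_sigma_lateral,
      psf_sigma_axial = psf_sigma_axial,
      background_level = background_level,
      read_noise_sd = read_noise_sd,
      bit_depth = as.integer(bit_depth)
    ),
    class = "acquisition_params"
  )
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat("Acquisition parameters\n")
  cat(sprintf("  pixel size      : %g um/px\n", x$pixel_size))
  cat(sprintf("  z step          : %g um/slice\n", x$z_step))
  cat(sprintf("  frame interval  : %g s (%.3g fps)\n",
              x$frame_interval, 1 / x$frame_interval))
  cat(sprintf("  image shape     : %s\n", paste(x$image_shape, collapse = " x ")))
  cat(sprintf("  PSF sigma       : %g px lateral, %g slices axial\n",
              x$psf_sigma_lateral, x$psf_sigma_axial))
  cat(sprintf("  background      : %g photons, read noise sd %g, %d-bit\n",
              x$background_level, x$read_noise_sd, x$bit_depth))
  invisible(x)
}
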