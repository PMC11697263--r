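# Beam point-spread functions on the pixel grid.

psf_radii <- function(optics, support_px) {
  support_px <- check_odd(support_px, "support_px")
  h <- (support_px - 1L) / 2
  d <- ((-h):h) * optics$pixel_size_nm
  list(x = matrix(d, support_px, support_px, byrow = TRUE),
       y = matrix(d, support_px, support_px),
       half_extent_nm = (h + 0.5) * optics$pixel_size_nm)
}

#' Gaussian (confocal) excitation PSF
#'
#' Isotropic 2-D Gaussian with the configured FWHM, sampled at pixel
#' centres and normalised to unit sum.  The support must be large enough
#' that the analytically truncated mass is below 1e-4.
#'
#' @param optics An [optics_config()].
#' @param support_px Odd kernel size in pixels.
#' @return An [intensity_image()] kernel with unit sum.
#' @export
gaussian_psf <- function(optics, support_px) {
  g <- psf_radii(optics, support_px)
  sigma <- optics$gaussian_fwhm_nm / (2 * sqrt(2 * log(2)))
  # radial mass of a 2-D Gaussian beyond R is exp(-R^2 / (2 sigma^2))
  if (exp(-g$half_extent_nm^2 / (2 * sigma^2)) >= 1e-4)
    stopf("support_px too small: truncated Gaussian mass >= 1e-4",
          class = "phasorFSTM_truncation_error")
  k <- exp(-(g$x^2 + g$y^2) / (2 * sigma^2))
  intensity_image(k / sum(k), optics$pixel_size_nm)
}

#' Donut excitation PSF
#'
#' Laguerre-Gaussian-like ring profile I(r) proportional to
#' r^2 * exp(-r^2 / r_p^2), which is exactly zero at the centre and peaks
#' at radius `donut_peak_radius_nm`.  Normalised to unit sum.
#'
#' @inheritParams gaussian_psf
#' @return An [intensity_image()] kernel with unit sum and zero centre.
#' @export
donut_psf <- function(optics, support_px) {
  g <- psf_radii(optics, support_px)
  rp2 <- optics$donut_peak_radius_nm^2
  # mass of r^3 exp(-r^2/rp^2) beyond R relative to total:
  # (1 + R^2/rp^2) exp(-R^2/rp^2)
  u <- g$half_extent_nm^2 / rp2
  if ((1 + u) * exp(-u) >= 1e-4)
    stopf("support_px too small: truncated donut mass >= 1e-4",
          class = "phasorFSTM_truncation_error")
  r2 <- g$x^2 + g$y^2
  k <- r2 * exp(-r2 / rp2)
  intensity_image(k / sum(k), optics$pixel_size_nm)
}

#' Default PSF support for a given optical configuration
#'
#' Smallest odd kernel size whose truncated mass is safely below 1e-4 for
#' both beams.
#'
#' @param optics An [optics_config()].
#' @return Odd integer kernel size in pixels.
#' @export
default_support_px <- function(optics) {
  sigma <- optics$gaussian_fwhm_nm / (2 * sqrt(2 * log(2)))
  # solve exp(-R^2/(2 s^2)) < 1e-4 and (1 + R^2/rp^2) exp(-R^2/rp^2) < 1e-4
  r_gauss <- sigma * sqrt(2 * log(1e4))
  rp <- optics$donut_peak_radius_nm
  r_donut <- rp * sqrt(13)  # (1 + 13) exp(-13) ~ 3e-5
  r <- max(r_gauss, r_donut) * 1.1
  n <- 2L * as.integer(ceiling(r / optics$pixel_size_nm)) + 1L
  max(n, 3L)
}
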