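# Optical and photophysical configuration for the acquisition simulator.

#' Optical configuration of the dual-beam microscope
#'
#' Defaults emulate a 635 nm pulsed laser behind a 1.40 NA oil objective.
#' The confocal (Gaussian) channel FWHM defaults to 0.40 * lambda, i.e. the
#' measured resolution of a well-aligned confocal at this wavelength rather
#' than the ideal diffraction formula, so that resolution comparisons start
#' from a realistic baseline.  The donut ring radius defaults to
#' 0.6 * FWHM_gaussian.
#'
#' @param wavelength_nm Excitation wavelength (nm).
#' @param numerical_aperture Objective NA.
#' @param pixel_size_nm Lateral sampling (nm).
#' @param gaussian_fwhm_nm Confocal PSF full width at half maximum (nm).
#' @param donut_peak_radius_nm Radius of the donut intensity maximum (nm).
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(wavelength_nm = 635, numerical_aperture = 1.40,
                          pixel_size_nm = 40,
                          gaussian_fwhm_nm = 0.40 * wavelength_nm,
                          donut_peak_radius_nm = 0.6 * gaussian_fwhm_nm) {
  vals <- c(wavelength_nm, numerical_aperture, pixel_size_nm,
            gaussian_fwhm_nm, donut_peak_radius_nm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stopf("all optics parameters must be positive",
          class = "phasorFSTM_parameter_error")
  if (gaussian_fwhm_nm < pixel_size_nm)
    stopf("gaussian_fwhm_nm (%g) must be >= pixel_size_nm (%g) for adequate sampling",
          gaussian_fwhm_nm, pixel_size_nm, class = "phasorFSTM_parameter_error")
  structure(list(wavelength_nm = wavelength_nm,
                 numerical_aperture = numerical_aperture,
                 pixel_size_nm = pixel_size_nm,
                 gaussian_fwhm_nm = gaussian_fwhm_nm,
                 donut_peak_radius_nm = donut_peak_radius_nm),
            class = "optics_config")
}

#' Fluorescent dye specification
#'
#' @param name Dye label (unique within a dye set).
#' @param lifetime_ns Mono-exponential decay constant tau (ns, > 0).
#' @param brightness Expected detected photons per unit emitter density per
#'   beam pass (>= 0).
#' @return An object of class `dye_spec`.
#' @export
dye_spec <- function(name, lifetime_ns, brightness = 1) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stopf("name must be a non-empty string", class = "phasorFSTM_parameter_error")
  if (!is.finite(lifetime_ns) || lifetime_ns <= 0)
    stopf("lifetime_ns must be > 0", class = "phasorFSTM_parameter_error")
  if (!is.finite(brightness) || brightness < 0)
    stopf("brightness must be >= 0", class = "phasorFSTM_parameter_error")
  structure(list(name = name, lifetime_ns = lifetime_ns,
                 brightness = brightness), class = "dye_spec")
}

#' The four-dye reference set
#'
#' Mono-exponential lifetimes of the four organelle probes used throughout
#' the package examples: mitochondrion 0.3 ns, nucleus 1.0 ns, microtubule
#' 3.3 ns, lysosome 3.8 ns.
#'
#' @param brightness Common brightness for all four dyes.
#' @return A named list of [dye_spec()] objects.
#' @export
reference_dyes <- function(brightness = 1) {
  list(mitochondrion = dye_spec("mitochondrion", 0.3, brightness),
       nucleus       = dye_spec("nucleus", 1.0, brightness),
       microtubule   = dye_spec("microtubule", 3.3, brightness),
       lysosome      = dye_spec("lysosome", 3.8, brightness))
}

#' Gaussian instrument-response model
#'
#' The detection chain's temporal blur, modelled as a Gaussian of standard
#' deviation `sigma_ns` with a systematic offset.  The default 0.10 ns is
#' typical for a PMT + TCSPC chain.
#'
#' @param sigma_ns Standard deviation (ns, >= 0).
#' @param offset_ns Systematic shift of detection times (ns).
#' @return An object of class `irf_model`.
#' @export
irf_model <- function(sigma_ns = 0.10, offset_ns = 0) {
  if (!is.finite(sigma_ns) || sigma_ns < 0)
    stopf("sigma_ns must be >= 0", class = "phasorFSTM_parameter_error")
  structure(list(sigma_ns = sigma_ns, offset_ns = offset_ns),
            class = "irf_model")
}

check_dyes <- function(dyes) {
  if (!length(dyes) || !all(vapply(dyes, inherits, TRUE, "dye_spec")))
    stopf("dyes must be a non-empty list of dye_spec objects",
          class = "phasorFSTM_parameter_error")
  nm <- vapply(dyes, `[[`, "", "name")
  if (anyDuplicated(nm))
    stopf("dye names must be unique", class = "phasorFSTM_parameter_error")
  names(dyes) <- nm
  dyes
}
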