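# Per-pixel phasor transformation and reference calibration.
#
# The base angular frequency is taken per split window (omega = 2 pi h /
# window duration), not per full laser period: each demultiplexed window
# contains one complete fluorescence decay, and matching the harmonic to
# the window both maximises lifetime contrast and makes the phasor of a
# (window-truncated, renormalised) mono-exponential land exactly on the
# universal semicircle.

#' Per-pixel phasor transform of a decay stack
#'
#' For each pixel with counts `c_k` at bin-centre times `t_k`,
#' `g = sum(c_k cos(w t_k)) / sum(c_k)` and
#' `s = sum(c_k sin(w t_k)) / sum(c_k)` with
#' `w = 2 pi harmonic / (window_len * bin_width)`.  Pixels with fewer than
#' `min_photons` photons are flagged undefined (NA) rather than reported
#' with shot-noise-dominated coordinates.
#'
#' @param decay A [decay_stack()].
#' @param harmonic Positive integer harmonic (default 1).
#' @param min_photons Minimum photons for a defined phasor (default 10).
#' @return An object of class `phasor_field` with matrices `g`, `s`,
#'   `total`, logical `defined`, and scalars `omega` (rad/ns), `harmonic`.
#' @export
phasor_transform <- function(decay, harmonic = 1L, min_photons = 10) {
  harmonic <- as.integer(harmonic)
  if (harmonic < 1L) stopf("harmonic must be >= 1",
                           class = "phasorFSTM_parameter_error")
  L <- decay$window_len
  if (L < 2L) stopf("window must have at least 2 bins",
                    class = "phasorFSTM_parameter_error")
  dt <- decay$bin_width_ns
  omega <- 2 * pi * harmonic / (L * dt)
  t_k <- (seq_len(L) - 0.5) * dt
  d <- dim(decay$counts)
  C <- matrix(decay$counts, d[1L] * d[2L], L)
  tot <- rowSums(C)
  gnum <- as.numeric(C %*% cos(omega * t_k))
  snum <- as.numeric(C %*% sin(omega * t_k))
  g <- ifelse(tot > 0, gnum / tot, NA_real_)
  s <- ifelse(tot > 0, snum / tot, NA_real_)
  defined <- tot >= min_photons
  g[!defined] <- NA_real_
  s[!defined] <- NA_real_
  structure(list(g = matrix(g, d[1L], d[2L]),
                 s = matrix(s, d[1L], d[2L]),
                 total = matrix(tot, d[1L], d[2L]),
                 defined = matrix(defined, d[1L], d[2L]),
                 omega = omega, harmonic = harmonic,
                 min_photons = min_photons,
                 window_len = L, bin_width_ns = dt,
                 beam_label = decay$beam_label,
                 pixel_size_nm = decay$pixel_size_nm,
                 calibrated = FALSE),
            class = "phasor_field")
}

#' Theoretical phasor of a mono-exponential decay
#'
#' `g = 1 / (1 + (w tau)^2)`, `s = w tau / (1 + (w tau)^2)`: the universal
#' semicircle centred at (0.5, 0) with radius 0.5.
#'
#' @param tau_ns Lifetime(s), >= 0 (vectorised).
#' @param omega Angular frequency (rad/ns).
#' @return A two-column matrix with columns `g` and `s`.
#' @export
theoretical_phasor <- function(tau_ns, omega) {
  if (any(tau_ns < 0)) stopf("tau_ns must be >= 0",
                             class = "phasorFSTM_parameter_error")
  wt <- omega * tau_ns
  cbind(g = 1 / (1 + wt^2), s = wt / (1 + wt^2))
}

phasor_of_histogram <- function(counts, bin_width_ns, omega) {
  tot <- sum(counts)
  if (tot <= 0) stopf("reference histogram has zero photons",
                      class = "phasorFSTM_calibration_error")
  t_k <- (seq_along(counts) - 0.5) * bin_width_ns
  complex(real = sum(counts * cos(omega * t_k)) / tot,
          imaginary = sum(counts * sin(omega * t_k)) / tot)
}

#' Calibrate a phasor field against a lifetime standard
#'
#' Computes the complex correction `z_theory(tau_ref) / z_measured(ref)`
#' from a reference decay of known lifetime (same timing and window as the
#' field) and applies the resulting rotation + scaling to every defined
#' pixel.  This removes the common pulse-position phase and IRF modulation.
#'
#' @param field A [phasor_transform()] result.
#' @param reference_decay Numeric 1-D histogram of the reference dye over
#'   the same window.
#' @param tau_ref_ns Known reference lifetime (ns, > 0).
#' @return List with elements `field` (calibrated `phasor_field`) and
#'   `record` (a `calibration_record` with `tau_ref_ns`, `measured`,
#'   `phase_correction` in radians, and `modulation_correction`).
#' @export
calibrate_phasor <- function(field, reference_decay, tau_ref_ns) {
  if (tau_ref_ns <= 0) stopf("tau_ref_ns must be > 0",
                             class = "phasorFSTM_parameter_error")
  zm <- phasor_of_histogram(reference_decay, field$bin_width_ns, field$omega)
  th <- theoretical_phasor(tau_ref_ns, field$omega)
  zt <- complex(real = th[1L, "g"], imaginary = th[1L, "s"])
  corr <- zt / zm
  z <- complex(real = field$g, imaginary = field$s) * corr
  field$g <- matrix(Re(z), nrow(field$g), ncol(field$g))
  field$s <- matrix(Im(z), nrow(field$s), ncol(field$s))
  field$calibrated <- TRUE
  record <- structure(list(tau_ref_ns = tau_ref_ns,
                           measured = c(g = Re(zm), s = Im(zm)),
                           phase_correction = Arg(corr),
                           modulation_correction = Mod(corr)),
                      class = "calibration_record")
  list(field = field, record = record)
}

#' Median-smooth a phasor field
#'
#' Applies a square median filter to `g` and `s` independently over defined
#' pixels (undefined pixels stay undefined and are excluded from their
#' neighbours' medians).  Photon totals are unchanged.  Median smoothing of
#' phasor coordinates is the standard shot-noise reduction used before
#' gating.
#'
#' @param field A `phasor_field`.
#' @param kernel_px Odd kernel size (1 = identity).
#' @param passes Number of filter passes.
#' @return The smoothed `phasor_field`.
#' @export
smooth_phasor <- function(field, kernel_px = 3L, passes = 1L) {
  field$g <- median_filter_na(field$g, kernel_px, passes)
  field$s <- median_filter_na(field$s, kernel_px, passes)
  field
}

#' Fit a mono-exponential lifetime to a decay histogram
#'
#' Count-weighted least squares on the log counts over bins at and past
#' `fit_start_bin` (0-based, relative to the histogram), which is the
#' standard tail fit once the IRF-contaminated rise is excluded.
#'
#' @param decay Numeric 1-D histogram.
#' @param bin_width_ns Bin width (ns).
#' @param fit_start_bin 0-based first bin of the fit range.
#' @param min_counts Bins with fewer counts are excluded (default 5):
#'   dropping empty bins from a log fit biases the sparse far tail upward,
#'   so the fit is restricted to bins where the log transform is
#'   well-behaved (the count weighting already dominates there).
#' @return Estimated lifetime `tau_hat` (ns, > 0).
#' @export
fit_monoexp <- function(decay, bin_width_ns, fit_start_bin = 0L,
                        min_counts = 5) {
  k <- seq_along(decay) - 1L
  keep <- k >= fit_start_bin & decay >= min_counts
  if (sum(keep) < 2L) {
    keep <- k >= fit_start_bin & decay > 0
    if (sum(keep) < 2L)
      stopf("need at least 2 non-empty bins past fit_start_bin",
            class = "phasorFSTM_fit_error")
  }
  tt <- (k[keep] + 0.5) * bin_width_ns
  y <- log(decay[keep])
  w <- decay[keep]
  fit <- stats::lm.wfit(cbind(1, tt), y, w)
  slope <- fit$coefficients[2L]
  # a slope this shallow would mean tau > 1e10 ns: not a decay
  if (!is.finite(slope) || slope >= -1e-10)
    stopf("decay tail is not decreasing; cannot fit a lifetime",
          class = "phasorFSTM_fit_error")
  as.numeric(-1 / slope)
}
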