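# Data model for time-resolved image stacks.
#
# Conventions: arrays are rows x cols x time-bins; time-bin indices exposed
# to users (pulse positions, boundaries, window origins) are 0-based, and
# bin b covers the half-open interval [b * dt, (b + 1) * dt) with
# representative time at the bin centre.  Pixel (r, c) of an image is
# centred at physical position ((c - 0.5) * px, (r - 0.5) * px) nm.

#' Timing metadata for a TCSPC acquisition
#'
#' Describes the laser pulse period, the number of TCSPC time channels, and
#' the positions (bin indices, 0-based) of the two temporally delayed
#' excitation pulses: the Gaussian pulse and the later donut pulse.  The
#' donut pulse bin doubles as the default boundary for temporal
#' demultiplexing.
#'
#' @param period_ns Laser pulse period T in nanoseconds.
#' @param n_bins Number of TCSPC time channels (>= 2).
#' @param gaussian_pulse_bin 0-based bin index of the Gaussian pulse peak.
#' @param donut_pulse_bin 0-based bin index of the donut pulse peak; must be
#'   strictly greater than `gaussian_pulse_bin` and less than `n_bins`.
#' @param bin_width_ns Width of one time channel; defaults to
#'   `period_ns / n_bins` and must equal it to within 1e-9.
#' @return An object of class `timing_config`.
#' @examples
#' timing_config(period_ns = 25, n_bins = 256,
#'               gaussian_pulse_bin = 4, donut_pulse_bin = 128)
#' @export
timing_config <- function(period_ns = 25, n_bins = 256L,
                          gaussian_pulse_bin = 4L, donut_pulse_bin = 128L,
                          bin_width_ns = period_ns / n_bins) {
  n_bins <- as.integer(n_bins)
  gaussian_pulse_bin <- as.integer(gaussian_pulse_bin)
  donut_pulse_bin <- as.integer(donut_pulse_bin)
  if (n_bins < 2L)
    stopf("n_bins must be >= 2", class = "phasorFSTM_parameter_error")
  if (abs(bin_width_ns * n_bins - period_ns) > 1e-9)
    stopf("bin_width_ns * n_bins must equal period_ns (got %g vs %g)",
          bin_width_ns * n_bins, period_ns,
          class = "phasorFSTM_parameter_error")
  if (!(0L <= gaussian_pulse_bin && gaussian_pulse_bin < donut_pulse_bin &&
        donut_pulse_bin < n_bins))
    stopf("pulse bins must satisfy 0 <= gaussian_pulse_bin < donut_pulse_bin < n_bins",
          class = "phasorFSTM_parameter_error")
  structure(list(period_ns = period_ns, n_bins = n_bins,
                 bin_width_ns = bin_width_ns,
                 gaussian_pulse_bin = gaussian_pulse_bin,
                 donut_pulse_bin = donut_pulse_bin),
            class = "timing_config")
}

#' Time-resolved photon-count image stack
#'
#' A rows x cols x n_bins array of non-negative integer photon counts with
#' timing metadata and the lateral pixel size.
#'
#' @param counts Integer array, rows x cols x `timing$n_bins`.
#' @param timing A [timing_config()].
#' @param pixel_size_nm Lateral sampling in nanometres (> 0).
#' @return An object of class `tcspc_stack`.
#' @export
tcspc_stack <- function(counts, timing, pixel_size_nm) {
  s <- structure(list(counts = counts, timing = timing,
                      pixel_size_nm = pixel_size_nm),
                 class = "tcspc_stack")
  bad <- validate_stack(s)
  if (length(bad)) stopf("invalid tcspc_stack: %s", paste(bad, collapse = "; "),
                         class = "phasorFSTM_validation_error")
  s
}

#' Validate a TCSPC stack
#'
#' Checks every invariant of the stack data model and reports violations as
#' human-readable strings instead of raising conditions.
#'
#' @param stack An object resembling a `tcspc_stack`.
#' @return A character vector of violation descriptions; empty when valid.
#' @export
validate_stack <- function(stack) {
  v <- character()
  cn <- stack$counts
  if (!is.array(cn) || length(dim(cn)) != 3L) {
    return("counts: must be a 3-dimensional array (rows x cols x bins)")
  }
  if (anyNA(cn) || any(!is.finite(cn)))
    v <- c(v, "counts: all values must be finite")
  else {
    if (any(cn < 0))
      v <- c(v, "counts: non-negativity violated (negative photon count)")
    if (any(cn != round(cn)))
      v <- c(v, "counts: values must be integers")
  }
  tm <- stack$timing
  if (!inherits(tm, "timing_config")) {
    v <- c(v, "timing: missing or not a timing_config")
  } else {
    if (dim(cn)[3L] != tm$n_bins)
      v <- c(v, sprintf("counts: third dimension (%d) must equal timing$n_bins (%d)",
                        dim(cn)[3L], tm$n_bins))
    if (tm$n_bins < 2L) v <- c(v, "timing: n_bins must be >= 2")
    if (abs(tm$bin_width_ns * tm$n_bins - tm$period_ns) > 1e-9)
      v <- c(v, "timing: bin_width_ns * n_bins must equal period_ns")
    if (!(0L <= tm$gaussian_pulse_bin && tm$gaussian_pulse_bin < tm$donut_pulse_bin &&
          tm$donut_pulse_bin < tm$n_bins))
      v <- c(v, "timing: pulse ordering 0 <= gaussian_pulse_bin < donut_pulse_bin < n_bins violated")
  }
  px <- stack$pixel_size_nm
  if (!is.numeric(px) || length(px) != 1L || !is.finite(px) || px <= 0)
    v <- c(v, "pixel_size_nm: must be a single positive number")
  v
}

#' Plain intensity image
#'
#' A rows x cols matrix of non-negative finite values (photon counts or
#' weights) with its lateral pixel size.
#'
#' @param values Non-negative numeric matrix.
#' @param pixel_size_nm Lateral sampling in nanometres (> 0).
#' @return An object of class `intensity_image`.
#' @export
intensity_image <- function(values, pixel_size_nm) {
  if (!is.matrix(values) || anyNA(values) || any(!is.finite(values)))
    stopf("values must be a finite numeric matrix",
          class = "phasorFSTM_validation_error")
  if (any(values < 0))
    stopf("values must be non-negative", class = "phasorFSTM_validation_error")
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0)
    stopf("pixel_size_nm must be positive", class = "phasorFSTM_validation_error")
  structure(list(values = values, pixel_size_nm = pixel_size_nm),
            class = "intensity_image")
}

#' Single-beam decay stack
#'
#' A window of a parent [tcspc_stack()] along the time axis, re-origined so
#' its first bin corresponds to parent bin `window_origin_bin`.  Produced by
#' [split_stack()].
#'
#' @param counts rows x cols x window_len integer array.
#' @param window_origin_bin 0-based parent bin of this window's first bin.
#' @param bin_width_ns Time channel width (ns).
#' @param beam_label Either `"gaussian"` or `"donut"`.
#' @param pixel_size_nm Lateral sampling (nm).
#' @return An object of class `decay_stack`.
#' @export
decay_stack <- function(counts, window_origin_bin, bin_width_ns, beam_label,
                        pixel_size_nm) {
  beam_label <- match.arg(beam_label, c("gaussian", "donut"))
  if (!is.array(counts) || length(dim(counts)) != 3L || any(counts < 0))
    stopf("counts must be a non-negative 3-d array",
          class = "phasorFSTM_validation_error")
  structure(list(counts = counts,
                 window_origin_bin = as.integer(window_origin_bin),
                 window_len = dim(counts)[3L],
                 bin_width_ns = bin_width_ns,
                 beam_label = beam_label,
                 pixel_size_nm = pixel_size_nm),
            class = "decay_stack")
}

#' @export
print.timing_config <- function(x, ...) {
  cat(sprintf("TCSPC timing: T = %g ns, %d bins (dt = %.4g ns), pulses at bins %d (Gaussian) / %d (donut)\n",
              x$period_ns, x$n_bins, x$bin_width_ns,
              x$gaussian_pulse_bin, x$donut_pulse_bin))
  invisible(x)
}

#' @export
print.tcspc_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("tcspc_stack: %d x %d pixels x %d bins, %s photons, pixel %g nm\n",
              d[1L], d[2L], d[3L], format(sum(x$counts), big.mark = ","),
              x$pixel_size_nm))
  print(x$timing)
  invisible(x)
}

#' @export
print.decay_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("decay_stack (%s beam): %d x %d pixels x %d bins from parent bin %d, %s photons\n",
              x$beam_label, d[1L], d[2L], d[3L], x$window_origin_bin,
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Per-pixel photon totals of a stack window
#'
#' @param x A [tcspc_stack()], [decay_stack()], or bare 3-d counts array.
#' @return rows x cols matrix of photon sums over the time axis.
#' @export
pixel_totals <- function(x) {
  cn <- if (inherits(x, c("tcspc_stack", "decay_stack"))) x$counts else x
  d <- dim(cn)
  matrix(rowSums(matrix(cn, d[1L] * d[2L], d[3L])), d[1L], d[2L])
}
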