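# Temporal demultiplexing: locate the donut-pulse boundary in the arrival
# time axis and split the stack into two realigned single-beam windows.
#
# Boundary convention: the boundary bin belongs to the donut window
# (half-open partition [0, b) / [b, n_bins)), so the donut pulse peak bin
# carries donut photons and per-pixel photon conservation is exact.

#' Global decay histogram
#'
#' Sum of the per-pixel decay histograms over all pixels.
#'
#' @param stack A [tcspc_stack()] or [decay_stack()].
#' @return Numeric vector over the stack's time bins; its sum equals the
#'   stack's total photon count exactly.
#' @export
global_decay <- function(stack) {
  cn <- stack$counts
  d <- dim(cn)
  colSums(matrix(cn, d[1L] * d[2L], d[3L]))
}

#' Detect the Gaussian/donut boundary bin
#'
#' Smooths the global decay with a 3-bin moving average and locates the two
#' excitation pulse peaks as the two most prominent local maxima separated
#' by more than 10 bins; the later peak is the donut pulse and its bin is
#' the boundary.  The boundary is a property of the optical setup, so it is
#' identical across frames of the same configuration.
#'
#' @param stack A [tcspc_stack()].
#' @param min_prominence Minimum prominence of the secondary peak as a
#'   fraction of the primary peak height (default 0.05).
#' @return 0-based boundary bin index.
#' @export
detect_boundary <- function(stack, min_prominence = 0.05) {
  h <- global_decay(stack)
  n <- length(h)
  sm <- as.numeric(stats::filter(h, rep(1 / 3, 3), sides = 2))
  sm[1L] <- h[1L]; sm[n] <- h[n]
  i <- 2:(n - 1L)
  is_max <- c(FALSE, sm[i] > sm[i - 1L] & sm[i] >= sm[i + 1L], FALSE)
  peaks <- which(is_max)
  if (!length(peaks))
    stopf("no pulse peaks found in the global decay",
          class = "phasorFSTM_detection_error")
  ord <- peaks[order(sm[peaks], decreasing = TRUE)]
  p1 <- ord[1L]
  p2 <- ord[abs(ord - p1) > 10L][1L]
  if (is.na(p2))
    stopf("no second pulse peak found (single-pulse acquisition?)",
          class = "phasorFSTM_detection_error")
  lo <- min(p1, p2); hi <- max(p1, p2)
  valley <- min(sm[lo:hi])
  prominence <- min(sm[p1], sm[p2]) - valley
  if (prominence < min_prominence * max(sm[p1], sm[p2]))
    stopf("secondary pulse peak prominence %.3g below threshold %.3g",
          prominence, min_prominence * max(sm[p1], sm[p2]),
          class = "phasorFSTM_detection_error")
  # The smoothed lobe maximum can trail the pulse by a few bins when the
  # decay is slow relative to the IRF (the top of the lobe is nearly flat);
  # the pulse channel itself is where the histogram rises fastest.  The IRF
  # spreads that rise over ~2 bins whose increments are comparable, so take
  # the leading edge: the first bin before the lobe peak whose increment
  # reaches half the largest increment.  This is stable across frames.
  lo_k <- max(2L, hi - 10L)
  jumps <- h[lo_k:hi] - h[(lo_k - 1L):(hi - 1L)]
  b1 <- lo_k + which(jumps >= 0.5 * max(jumps))[1L] - 1L
  as.integer(b1 - 1L)  # 0-based
}

#' Split a stack at the boundary into Gaussian and donut decay stacks
#'
#' The Gaussian window is parent bins `[0, boundary)`; the donut window is
#' `[boundary, n_bins)`, re-origined so its first bin is the boundary.  The
#' partition is exact and lossless: per-pixel integer sums of the two
#' outputs equal the parent sums.
#'
#' @param stack A [tcspc_stack()].
#' @param boundary_bin 0-based boundary bin (e.g. from [detect_boundary()]);
#'   must satisfy `gaussian_pulse_bin < boundary_bin < n_bins`.
#' @return List with elements `gaussian` and `donut`, both [decay_stack()].
#' @export
split_stack <- function(stack, boundary_bin) {
  tm <- stack$timing
  b <- as.integer(boundary_bin)
  if (b <= tm$gaussian_pulse_bin || b >= tm$n_bins)
    stopf("boundary_bin must lie in (gaussian_pulse_bin, n_bins); got %d", b,
          class = "phasorFSTM_parameter_error")
  g <- decay_stack(stack$counts[, , seq_len(b), drop = FALSE],
                   window_origin_bin = 0L, bin_width_ns = tm$bin_width_ns,
                   beam_label = "gaussian", pixel_size_nm = stack$pixel_size_nm)
  d <- decay_stack(stack$counts[, , (b + 1L):tm$n_bins, drop = FALSE],
                   window_origin_bin = b, bin_width_ns = tm$bin_width_ns,
                   beam_label = "donut", pixel_size_nm = stack$pixel_size_nm)
  list(gaussian = g, donut = d)
}
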