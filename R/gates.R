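# Circular phasor gates and per-pixel component assignment.
#
# Assignment is hard (all of a pixel's photons go to one dye): a pixel is
# assigned to the gate containing its (g, s); if several circles contain
# it the nearest centre wins, with the lower dye index as the final
# tie-break.  Fractional multi-component decomposition within one pixel is
# out of scope.

#' Circular gate in phasor space
#'
#' @param label Dye identity.
#' @param center Length-2 numeric (g0, s0), within `[-1.1, 1.1]^2`.
#' @param radius Positive radius in phasor units.
#' @return An object of class `phasor_gate`.
#' @export
phasor_gate <- function(label, center, radius) {
  if (radius <= 0) stopf("radius must be > 0",
                         class = "phasorFSTM_parameter_error")
  if (length(center) != 2L || any(abs(center) > 1.1))
    stopf("gate center must lie within [-1.1, 1.1]^2",
          class = "phasorFSTM_parameter_error")
  structure(list(label = label, center = as.numeric(center),
                 radius = radius), class = "phasor_gate")
}

#' Build gates from known lifetimes
#'
#' One gate per dye, centred at [theoretical_phasor()] of its lifetime at
#' the field's angular frequency, all with the same radius.  Gates whose
#' centres are closer than `2 * radius` overlap; this is reported as a
#' warning (the nearest-centre rule disambiguates the overlap region).
#'
#' @param dyes Named list of [dye_spec()] with distinct lifetimes.
#' @param omega Angular frequency (rad/ns) of the phasor field the gates
#'   will be applied to.
#' @param radius Common gate radius (phasor units, default 0.1).
#' @return List of [phasor_gate()] objects, in dye order.
#' @export
gates_from_lifetimes <- function(dyes, omega, radius = 0.1) {
  dyes <- check_dyes(dyes)
  taus <- vapply(dyes, `[[`, 0, "lifetime_ns")
  if (anyDuplicated(taus))
    stopf("dye lifetimes must be distinct", class = "phasorFSTM_parameter_error")
  th <- theoretical_phasor(taus, omega)
  gates <- lapply(seq_along(dyes), function(i)
    phasor_gate(names(dyes)[i], th[i, ], radius))
  if (length(gates) > 1L) {
    ctr <- t(vapply(gates, `[[`, numeric(2), "center"))
    dmin <- min(stats::dist(ctr))
    if (dmin < 2 * radius)
      warning(sprintf(
        "phasor gates overlap (closest centres %.3f apart < 2 * radius %.3f); nearest-centre assignment disambiguates",
        dmin, radius), call. = FALSE)
  }
  gates
}

#' Recenter gates on the observed phasor clusters
#'
#' The theoretical semicircle positions locate each dye's gate, but the
#' observed cluster centres also depend on concentration (mixture pixels
#' move along chords) and residual calibration error.  This mirrors the
#' practice of placing the extraction circles on the visible clusters:
#' starting from the supplied gates, pixels are partitioned to their
#' nearest centre (Lloyd iterations restricted to pixels within
#' `capture_radius` of some centre, so empty phasor background cannot drag
#' a gate) and each centre moves to the photon-weighted mean of its
#' partition until the centres stabilise.  Nearest-centre partitioning
#' keeps overlapping gates split at their bisector instead of letting them
#' collapse onto a common centroid.  A gate that captures no pixels keeps
#' its centre.
#'
#' @param field A `phasor_field` (calibrated, typically smoothed).
#' @param gates Initial gates, e.g. from [gates_from_lifetimes()].
#' @param radius Optional new radius applied to all gates after refinement
#'   (default: keep each gate's radius).
#' @param capture_radius Pixels farther than this from every current
#'   centre are ignored during refinement (default: the largest gate
#'   radius).
#' @param max_iter Maximum Lloyd sweeps (default 25).
#' @return The refined gate list.
#' @export
refine_gates <- function(field, gates, radius = NULL,
                         capture_radius = NULL, max_iter = 25L) {
  g <- as.numeric(field$g); s <- as.numeric(field$s)
  w <- as.numeric(field$total)
  ok <- !is.na(g) & !is.na(s)
  g <- g[ok]; s <- s[ok]; w <- w[ok]
  if (is.null(capture_radius))
    capture_radius <- max(vapply(gates, `[[`, 0, "radius"))
  if (length(g)) {
    ctr <- t(vapply(gates, `[[`, numeric(2), "center"))
    for (it in seq_len(max_iter)) {
      D <- vapply(seq_len(nrow(ctr)), function(i)
        (g - ctr[i, 1L])^2 + (s - ctr[i, 2L])^2, numeric(length(g)))
      D <- matrix(D, ncol = nrow(ctr))
      nearest <- max.col(-D, ties.method = "first")
      dmin <- D[cbind(seq_along(nearest), nearest)]
      nearest[dmin > capture_radius^2] <- 0L
      moved <- FALSE
      for (i in seq_len(nrow(ctr))) {
        sel <- nearest == i
        if (!any(sel)) next
        new_ctr <- pmin(pmax(c(sum(g[sel] * w[sel]), sum(s[sel] * w[sel])) /
                               sum(w[sel]), -1.1), 1.1)
        if (sum((new_ctr - ctr[i, ])^2) > 1e-12) moved <- TRUE
        ctr[i, ] <- new_ctr
      }
      if (!moved) break
    }
    for (i in seq_along(gates)) gates[[i]]$center <- ctr[i, ]
  }
  if (!is.null(radius))
    gates <- lapply(gates, function(gt) { gt$radius <- radius; gt })
  gates
}

#' Assign pixels to gates
#'
#' @param field A `phasor_field` (typically calibrated and smoothed).
#' @param gates List of [phasor_gate()].
#' @return Integer label matrix: gate index (1-based) per pixel, 0 for
#'   pixels outside every gate or with undefined phasor.  Gate labels are
#'   attached as the `"labels"` attribute.
#' @export
assign_pixels <- function(field, gates) {
  if (!length(gates)) stopf("need at least one gate",
                            class = "phasorFSTM_parameter_error")
  nr <- nrow(field$g); nc <- ncol(field$g)
  g <- as.numeric(field$g); s <- as.numeric(field$s)
  D <- matrix(Inf, nr * nc, length(gates))
  for (i in seq_along(gates)) {
    gt <- gates[[i]]
    di <- sqrt((g - gt$center[1L])^2 + (s - gt$center[2L])^2)
    di[is.na(di) | di > gt$radius] <- Inf
    D[, i] <- di
  }
  lab <- max.col(-D, ties.method = "first")
  lab[!is.finite(apply(D, 1L, min))] <- 0L
  out <- matrix(as.integer(lab), nr, nc)
  attr(out, "labels") <- vapply(gates, function(x) as.character(x$label), "")
  out
}

#' Extract per-dye component images from both beam windows
#'
#' For each dye, the Gaussian-beam image `I_g` holds the Gaussian-window
#' photon totals of pixels assigned to that dye (zero elsewhere), and
#' likewise `I_d` for the donut window.  Each beam is gated by its own
#' phasor field: pass a single label map to apply it to both beams, or a
#' list `list(gaussian =, donut =)` with one map per beam.
#'
#' @param labels Integer label map from [assign_pixels()], or a list with
#'   elements `gaussian` and `donut`.
#' @param gaussian_decay,donut_decay The two [decay_stack()] windows.
#' @return An object of class `component_images`: `images` is a named list
#'   (per dye) of lists with [intensity_image()] elements `gaussian` and
#'   `donut`; `bookkeeping` carries exact integer photon accounting
#'   (per-beam totals, per-dye assigned counts, unassigned counts).
#' @export
extract_components <- function(labels, gaussian_decay, donut_decay) {
  if (is.list(labels) && !is.matrix(labels)) {
    lab_g <- labels$gaussian; lab_d <- labels$donut
  } else {
    lab_g <- labels; lab_d <- labels
  }
  dye_names <- attr(lab_g, "labels")
  if (is.null(dye_names))
    dye_names <- as.character(seq_len(max(1L, max(lab_g, lab_d))))
  tg <- pixel_totals(gaussian_decay)
  td <- pixel_totals(donut_decay)
  if (!identical(dim(tg), dim(lab_g)[1:2]) || !identical(dim(td), dim(lab_d)[1:2]))
    stopf("label map and decay stack shapes disagree",
          class = "phasorFSTM_parameter_error")
  px <- gaussian_decay$pixel_size_nm
  images <- list()
  assigned <- matrix(0, length(dye_names), 2L,
                     dimnames = list(dye_names, c("gaussian", "donut")))
  for (i in seq_along(dye_names)) {
    ig <- tg * (lab_g == i)
    id <- td * (lab_d == i)
    assigned[i, ] <- c(sum(ig), sum(id))
    images[[dye_names[i]]] <- list(gaussian = intensity_image(ig, px),
                                   donut = intensity_image(id, px))
  }
  bk <- list(total = sum(tg) + sum(td),
             gaussian_total = sum(tg), donut_total = sum(td),
             assigned = assigned,
             unassigned = c(gaussian = sum(tg) - sum(assigned[, 1L]),
                            donut = sum(td) - sum(assigned[, 2L])))
  structure(list(images = images, bookkeeping = bk),
            class = "component_images")
}
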