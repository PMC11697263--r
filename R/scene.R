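# Ground-truth scene geometry for the acquisition simulator.
#
# Amplitude semantics (documented per primitive):
#   * bead: `amplitude` is the TOTAL emitter density deposited (so a bead's
#     expected photon yield per beam is amplitude * brightness);
#   * blob:  `amplitude` is likewise the total (Gaussian footprint,
#     discretely normalised);
#   * filament: `amplitude` is the density PER PIXEL of the rasterised
#     ribbon (pixels whose centre lies within width/2 of the polyline).

scene_structure <- function(type, dye, amplitude, ...) {
  if (!is.character(dye) || length(dye) != 1L)
    stopf("dye must be a dye name (string)", class = "phasorFSTM_parameter_error")
  if (!is.finite(amplitude) || amplitude < 0)
    stopf("amplitude must be >= 0", class = "phasorFSTM_parameter_error")
  structure(c(list(type = type, dye = dye, amplitude = amplitude),
              list(...)), class = "scene_structure")
}

#' Scene primitives
#'
#' Constructors for the emitter-geometry primitives a [scene()] is built
#' from.  Coordinates are physical nanometres with x along image columns
#' and y along rows, origin at the top-left corner of the field.
#'
#' @param center_nm Length-2 numeric, (x, y) in nm.
#' @param diameter_nm Bead diameter (nm, > 0).
#' @param dye Name of the dye this structure is labelled with.
#' @param amplitude Emitter density (see Details in [scene()]).
#' @return A `scene_structure` object.
#' @export
scene_bead <- function(center_nm, diameter_nm, dye, amplitude) {
  if (diameter_nm <= 0) stopf("diameter_nm must be > 0",
                              class = "phasorFSTM_parameter_error")
  scene_structure("bead", dye, amplitude, center_nm = center_nm,
                  diameter_nm = diameter_nm)
}

#' @rdname scene_bead
#' @param points_nm n x 2 matrix of polyline vertices (nm).
#' @param width_nm Ribbon width (nm, > 0).
#' @export
scene_filament <- function(points_nm, width_nm, dye, amplitude) {
  points_nm <- as.matrix(points_nm)
  if (nrow(points_nm) < 2L || ncol(points_nm) != 2L)
    stopf("points_nm must be an n x 2 matrix with n >= 2",
          class = "phasorFSTM_parameter_error")
  if (width_nm <= 0) stopf("width_nm must be > 0",
                           class = "phasorFSTM_parameter_error")
  scene_structure("filament", dye, amplitude, points_nm = points_nm,
                  width_nm = width_nm)
}

#' @rdname scene_bead
#' @param sigma_nm Gaussian footprint standard deviation (nm, > 0).
#' @export
scene_blob <- function(center_nm, sigma_nm, dye, amplitude) {
  if (sigma_nm <= 0) stopf("sigma_nm must be > 0",
                           class = "phasorFSTM_parameter_error")
  scene_structure("blob", dye, amplitude, center_nm = center_nm,
                  sigma_nm = sigma_nm)
}

#' Emitter scene
#'
#' A field of labelled structures with a physical extent.  Each primitive
#' must lie within the extent.
#'
#' @param extent_nm Length-2 numeric, (width, height) in nm.
#' @param structures List of [scene_bead()], [scene_filament()], or
#'   [scene_blob()] objects.
#' @return An object of class `scene`.
#' @export
scene <- function(extent_nm, structures = list()) {
  if (length(extent_nm) != 2L || any(extent_nm <= 0))
    stopf("extent_nm must be two positive numbers",
          class = "phasorFSTM_parameter_error")
  for (s in structures) {
    if (!inherits(s, "scene_structure"))
      stopf("structures must be scene primitives",
            class = "phasorFSTM_parameter_error")
    pts <- switch(s$type, bead = , blob = rbind(s$center_nm),
                  filament = s$points_nm)
    if (any(pts[, 1L] < 0) || any(pts[, 1L] > extent_nm[1L]) ||
        any(pts[, 2L] < 0) || any(pts[, 2L] > extent_nm[2L]))
      stopf("scene structure lies outside the extent",
            class = "phasorFSTM_parameter_error")
  }
  structure(list(extent_nm = extent_nm, structures = structures),
            class = "scene")
}

# Rasterise a scene on a pixel grid: one density map per dye name present.
rasterize_scene <- function(scene, pixel_size_nm) {
  nc <- as.integer(round(scene$extent_nm[1L] / pixel_size_nm))
  nr <- as.integer(round(scene$extent_nm[2L] / pixel_size_nm))
  if (nr < 1L || nc < 1L)
    stopf("scene extent smaller than one pixel",
          class = "phasorFSTM_parameter_error")
  xc <- (seq_len(nc) - 0.5) * pixel_size_nm
  yc <- (seq_len(nr) - 0.5) * pixel_size_nm
  X <- matrix(xc, nr, nc, byrow = TRUE)
  Y <- matrix(yc, nr, nc)
  dyes <- unique(vapply(scene$structures, `[[`, "", "dye"))
  maps <- stats::setNames(lapply(dyes, function(d) matrix(0, nr, nc)), dyes)
  for (s in scene$structures) {
    m <- maps[[s$dye]]
    if (s$type == "bead") {
      r <- s$diameter_nm / 2
      if (s$diameter_nm <= pixel_size_nm) {
        # sub-pixel bead: bilinear deposit of the full amplitude
        fc <- s$center_nm[1L] / pixel_size_nm + 0.5
        fr <- s$center_nm[2L] / pixel_size_nm + 0.5
        fc <- min(max(fc, 1), nc); fr <- min(max(fr, 1), nr)
        c0 <- min(floor(fc), nc - 1L); r0 <- min(floor(fr), nr - 1L)
        wc <- fc - c0; wr <- fr - r0
        m[r0, c0]         <- m[r0, c0] + s$amplitude * (1 - wr) * (1 - wc)
        m[r0, c0 + 1L]    <- m[r0, c0 + 1L] + s$amplitude * (1 - wr) * wc
        m[r0 + 1L, c0]    <- m[r0 + 1L, c0] + s$amplitude * wr * (1 - wc)
        m[r0 + 1L, c0 + 1L] <- m[r0 + 1L, c0 + 1L] + s$amplitude * wr * wc
      } else {
        inside <- (X - s$center_nm[1L])^2 + (Y - s$center_nm[2L])^2 <= r^2
        if (!any(inside)) inside[which.min((X - s$center_nm[1L])^2 +
                                           (Y - s$center_nm[2L])^2)] <- TRUE
        m[inside] <- m[inside] + s$amplitude / sum(inside)
      }
    } else if (s$type == "blob") {
      k <- exp(-((X - s$center_nm[1L])^2 + (Y - s$center_nm[2L])^2) /
                 (2 * s$sigma_nm^2))
      m <- m + s$amplitude * k / sum(k)
    } else if (s$type == "filament") {
      d2 <- matrix(Inf, nr, nc)
      pts <- s$points_nm
      for (i in seq_len(nrow(pts) - 1L)) {
        p <- pts[i, ]; q <- pts[i + 1L, ]
        v <- q - p; L2 <- sum(v^2)
        tt <- if (L2 == 0) matrix(0, nr, nc) else
          pmin(pmax(((X - p[1L]) * v[1L] + (Y - p[2L]) * v[2L]) / L2, 0), 1)
        d2 <- pmin(d2, (X - (p[1L] + tt * v[1L]))^2 +
                       (Y - (p[2L] + tt * v[2L]))^2)
      }
      m[d2 <= (s$width_nm / 2)^2] <- m[d2 <= (s$width_nm / 2)^2] + s$amplitude
    }
    maps[[s$dye]] <- m
  }
  maps
}
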