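# Simplified organelle morphology: adaptive-threshold object identification,
# per-object 2-D shape descriptors, and skeleton branch/junction counts.

#' Identify objects by adaptive (local-mean) thresholding
#'
#' A pixel is foreground when its value exceeds the local mean over a
#' square window plus `offset`; foreground pixels are grouped into
#' 8-connected components and components smaller than `min_area_px` are
#' removed.  Raising `offset` never increases the object count.
#'
#' @param image An [intensity_image()] or matrix.
#' @param window_px Odd window size for the local mean (default 31).
#' @param offset Threshold offset above the local mean (default 0).
#' @param min_area_px Minimum component area in pixels (default 9).
#' @return Integer labelled object map (0 = background, 1..n = objects).
#' @export
identify_objects <- function(image, window_px = 31L, offset = 0,
                             min_area_px = 9L) {
  window_px <- check_odd(window_px, "window_px")
  if (window_px < 3L) stopf("window_px must be >= 3",
                            class = "phasorFSTM_parameter_error")
  v <- if (inherits(image, "intensity_image")) image$values else image
  local_mean <- box_mean_replicate(v, window_px)
  mask <- v > local_mean + offset
  lab <- label_components(mask)
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L])
    small <- which(areas < min_area_px)
    if (length(small)) lab[lab %in% small] <- 0L
    ids <- sort(unique(lab[lab > 0L]))
    lab <- matrix(match(lab, ids, nomatch = 0L), nrow(lab), ncol(lab))
  }
  lab
}

# Exact local box mean with replicate border padding, via an integral
# image (no FFT, so flat regions threshold exactly).
box_mean_replicate <- function(v, w) {
  h <- (w - 1L) %/% 2L
  nr <- nrow(v); nc <- ncol(v)
  ri <- pmin(pmax(seq_len(nr + 2L * h) - h, 1L), nr)
  ci <- pmin(pmax(seq_len(nc + 2L * h) - h, 1L), nc)
  P <- v[ri, ci, drop = FALSE]
  I <- rbind(0, apply(P, 2L, cumsum))
  I <- cbind(0, t(apply(I, 1L, cumsum)))
  i0 <- seq_len(nr); j0 <- seq_len(nc)
  (I[i0 + w, j0 + w, drop = FALSE] - I[i0, j0 + w, drop = FALSE] -
     I[i0 + w, j0, drop = FALSE] + I[i0, j0, drop = FALSE]) / w^2
}

# Crofton 4-direction perimeter of a binary mask (in pixel units).  Counts
# 2x2 neighbourhood configurations on the zero-padded mask and weights them
# with the standard integral-geometry coefficients, so the estimate is
# fixed and reproducible.
crofton_perimeter <- function(mask) {
  mask <- (mask > 0) * 1L
  nr <- nrow(mask); nc <- ncol(mask)
  A <- matrix(0L, nr + 2L, nc + 2L)
  A[2:(nr + 1L), 2:(nc + 1L)] <- mask
  up   <- rbind(0L, A[seq_len(nr + 1L), , drop = FALSE])
  left <- cbind(0L, A[, seq_len(nc + 1L), drop = FALSE])
  upleft <- rbind(0L, cbind(0L, A[seq_len(nr + 1L), seq_len(nc + 1L),
                                  drop = FALSE]))
  code <- A + 2L * up + 4L * left + 8L * upleft
  h <- tabulate(as.integer(code) + 1L, nbins = 16L)
  r2 <- sqrt(2)
  coefs <- c(0, pi / 4 * (1 + 1 / r2), pi / (4 * r2), pi / (2 * r2), 0,
             pi / 4 * (1 + 1 / r2), 0, pi / (4 * r2), pi / 4, pi / 2,
             pi / (4 * r2), pi / (4 * r2), pi / 4, pi / 2, 0, 0)
  sum(coefs * h)
}

# Aspect ratio from the central second moments (fitted-ellipse axes); a
# 1/12-pixel variance per axis accounts for the finite pixel footprint.
moment_aspect_ratio <- function(rows, cols) {
  mu20 <- stats::var(cols) * (length(cols) - 1) / length(cols) + 1 / 12
  mu02 <- stats::var(rows) * (length(rows) - 1) / length(rows) + 1 / 12
  mu11 <- mean((cols - mean(cols)) * (rows - mean(rows)))
  tr <- mu20 + mu02
  det <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (tr + det) / 2; l2 <- (tr - det) / 2
  if (l2 <= 0) Inf else sqrt(l1 / l2)
}

#' Per-object morphology report
#'
#' Area, Crofton perimeter, circularity (`4 pi A / P^2`), form factor
#' (`FF = 1 / circularity`; 1 for a disk, larger for elongated or irregular
#' shapes), and fitted-ellipse aspect ratio for every labelled object, plus
#' image-level counts and optional skeleton statistics of the full mask.
#'
#' @param objects Labelled object map from [identify_objects()].
#' @param pixel_size_nm Lateral pixel size (nm).
#' @param include_skeleton Also compute [skeleton_stats()] of the combined
#'   mask (default TRUE).
#' @return A `morphology_report` list: `objects` data.frame (id, area_um2,
#'   perimeter_um, circularity, form_factor, aspect_ratio), `n_objects`,
#'   `total_area_um2`, and optionally `skeleton` (branches, junctions).
#' @export
morphology_report <- function(objects, pixel_size_nm,
                              include_skeleton = TRUE) {
  n <- max(objects)
  px_um <- pixel_size_nm / 1000
  rows <- row(objects); cols <- col(objects)
  tab <- data.frame(id = integer(0), area_um2 = numeric(0),
                    perimeter_um = numeric(0), circularity = numeric(0),
                    form_factor = numeric(0), aspect_ratio = numeric(0))
  for (i in seq_len(n)) {
    sel <- objects == i
    area_px <- sum(sel)
    per_px <- crofton_perimeter(sel)
    circ <- if (per_px > 0) 4 * pi * area_px / per_px^2 else NA_real_
    tab <- rbind(tab, data.frame(
      id = i, area_um2 = area_px * px_um^2, perimeter_um = per_px * px_um,
      circularity = circ, form_factor = 1 / circ,
      aspect_ratio = moment_aspect_ratio(rows[sel], cols[sel])))
  }
  rep_ <- list(objects = tab, n_objects = n,
               total_area_um2 = sum(tab$area_um2))
  if (include_skeleton && n > 0L)
    rep_$skeleton <- skeleton_stats(objects > 0L)[c("branches", "junctions")]
  structure(rep_, class = "morphology_report")
}

# Zhang-Suen morphological thinning of a binary mask.
thin_mask <- function(mask) {
  m <- (mask > 0) * 1L
  nr <- nrow(m); nc <- ncol(m)
  pad <- function(x) {
    p <- matrix(0L, nr + 2L, nc + 2L)
    p[2:(nr + 1L), 2:(nc + 1L)] <- x
    p
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- pad(m)
      ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
      p2 <- p[ri - 1L, ci]; p3 <- p[ri - 1L, ci + 1L]; p4 <- p[ri, ci + 1L]
      p5 <- p[ri + 1L, ci + 1L]; p6 <- p[ri + 1L, ci]
      p7 <- p[ri + 1L, ci - 1L]; p8 <- p[ri, ci - 1L]; p9 <- p[ri - 1L, ci - 1L]
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
        (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
        (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
        (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      if (step == 1L) {
        cond <- p2 * p4 * p6 == 0L & p4 * p6 * p8 == 0L
      } else {
        cond <- p2 * p4 * p8 == 0L & p2 * p6 * p8 == 0L
      }
      del <- m == 1L & B >= 2L & B <= 6L & A == 1L & cond
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Skeleton branch and junction counts
#'
#' Thins the mask to a one-pixel-wide skeleton (Zhang-Suen), marks skeleton
#' pixels with three or more 8-connected skeleton neighbours as junction
#' pixels, merges adjacent junction pixels into single junctions, and
#' counts branches as the connected skeleton segments left after removing
#' junction pixels.  A straight bar gives 1 branch / 0 junctions; a "Y"
#' gives 3 branches / 1 junction.
#'
#' @param mask Non-empty binary matrix.
#' @return List with `branches`, `junctions`, and the `skeleton` matrix.
#' @export
skeleton_stats <- function(mask) {
  if (!any(mask > 0)) stopf("mask is empty",
                            class = "phasorFSTM_parameter_error")
  sk <- thin_mask(mask)
  nr <- nrow(sk); nc <- ncol(sk)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- sk
  ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
  nb <- p[ri - 1L, ci] + p[ri + 1L, ci] + p[ri, ci - 1L] + p[ri, ci + 1L] +
    p[ri - 1L, ci - 1L] + p[ri - 1L, ci + 1L] +
    p[ri + 1L, ci - 1L] + p[ri + 1L, ci + 1L]
  junction_px <- sk == 1L & nb >= 3L
  junctions <- max(label_components(junction_px))
  branch_map <- label_components(sk == 1L & !junction_px)
  list(branches = max(branch_map), junctions = junctions, skeleton = sk)
}
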