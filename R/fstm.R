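# Spatial modulation: weighted subtraction of the donut image from the
# Gaussian image, optional Richardson-Lucy deblurring, and multicolor
# composition.
#
# Negative residuals of the subtraction are clipped to zero; the
# super-resolved image is I_s = max(I_g - delta * I_d, 0) with delta = 2 by
# default.

#' Weighted pixel-by-pixel subtraction
#'
#' `output = max(i_g - delta * i_d, 0)` at every pixel.  The output is
#' everywhere `<= i_g` and pointwise non-increasing in `delta`.
#'
#' @param i_g,i_d [intensity_image()]s (or bare matrices) of matching
#'   shape: Gaussian-beam and donut-beam photons of one dye.
#' @param delta Non-negative weight coefficient (default 2).
#' @return An [intensity_image()] (or matrix, matching the input type).
#' @export
subtract_weighted <- function(i_g, i_d, delta = 2) {
  if (delta < 0) stopf("delta must be >= 0", class = "phasorFSTM_parameter_error")
  vg <- if (inherits(i_g, "intensity_image")) i_g$values else i_g
  vd <- if (inherits(i_d, "intensity_image")) i_d$values else i_d
  if (!identical(dim(vg), dim(vd)))
    stopf("image shapes disagree", class = "phasorFSTM_parameter_error")
  out <- pmax(vg - delta * vd, 0)
  if (inherits(i_g, "intensity_image"))
    intensity_image(out, i_g$pixel_size_nm)
  else out
}

# Local maxima of an image that stand out from the background; used to
# auto-detect bright spots for the delta heuristic.
find_spots <- function(values, min_rel = 0.3, max_spots = 20L) {
  nr <- nrow(values); nc <- ncol(values)
  if (nr < 3L || nc < 3L) return(matrix(numeric(0), 0L, 2L))
  inner <- values[2:(nr - 1L), 2:(nc - 1L)]
  is_max <- inner >= values[1:(nr - 2L), 2:(nc - 1L)] &
    inner >= values[3:nr, 2:(nc - 1L)] &
    inner >= values[2:(nr - 1L), 1:(nc - 2L)] &
    inner >= values[2:(nr - 1L), 3:nc] &
    inner >= values[1:(nr - 2L), 1:(nc - 2L)] &
    inner >= values[1:(nr - 2L), 3:nc] &
    inner >= values[3:nr, 1:(nc - 2L)] &
    inner >= values[3:nr, 3:nc] &
    inner >= min_rel * max(values) & inner > 0
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) return(matrix(numeric(0), 0L, 2L))
  idx <- idx + 1L  # back to full-image coordinates
  ord <- order(values[idx], decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  # suppress maxima closer than 3 px to a stronger one (plateau duplicates)
  keep <- rep(TRUE, nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!keep[i]) next
    if (i < nrow(idx)) {
      later <- (i + 1L):nrow(idx)
      d2 <- (idx[later, 1L] - idx[i, 1L])^2 + (idx[later, 2L] - idx[i, 2L])^2
      keep[later][d2 < 9] <- FALSE
    }
  }
  utils::head(idx[keep, , drop = FALSE], max_spots)
}

#' Choose a subtraction weight from candidates
#'
#' Heuristic: over a grid of candidate weights, pick the one minimising the
#' mean FWHM across auto-detected bright spots, subject to the energy
#' removed by clipping negatives staying below `max_clip_fraction` of the
#' total Gaussian intensity.  When no spot can be detected or no candidate
#' qualifies, returns 2 (the standard operating weight) with a warning.
#'
#' @inheritParams subtract_weighted
#' @param delta_grid Non-empty numeric grid of candidate weights (>= 0).
#' @param max_clip_fraction Clipped-energy budget (default 0.3).
#' @return The selected weight.
#' @export
auto_delta <- function(i_g, i_d, delta_grid = seq(0, 3, by = 0.25),
                       max_clip_fraction = 0.3) {
  if (!length(delta_grid) || any(delta_grid < 0))
    stopf("delta_grid must be non-empty and >= 0",
          class = "phasorFSTM_parameter_error")
  vg <- if (inherits(i_g, "intensity_image")) i_g$values else i_g
  vd <- if (inherits(i_d, "intensity_image")) i_d$values else i_d
  px <- if (inherits(i_g, "intensity_image")) i_g$pixel_size_nm else 1
  spots <- find_spots(vg)
  if (!nrow(spots)) {
    warning("no bright spots detected; falling back to delta = 2", call. = FALSE)
    return(2)
  }
  total_g <- sum(vg)
  half_len <- 12 * px
  mean_fwhm_at <- function(delta) {
    sub <- pmax(vg - delta * vd, 0)
    img <- intensity_image(sub, px)
    f <- numeric(0)
    for (k in seq_len(nrow(spots))) {
      cx <- (spots[k, 2L] - 0.5) * px; cy <- (spots[k, 1L] - 0.5) * px
      for (ln in list(rbind(c(cx - half_len, cy), c(cx + half_len, cy)),
                      rbind(c(cx, cy - half_len), c(cx, cy + half_len)))) {
        pm <- measure_fwhm(img, ln, sampling_nm = px / 4)
        if (pm$defined) f <- c(f, pm$fwhm_nm)
      }
    }
    if (!length(f)) NA_real_ else mean(f)
  }
  clipped <- vapply(delta_grid, function(d) sum(pmax(d * vd - vg, 0) *
                                                  (vg - d * vd < 0)), 0)
  ok <- clipped <= max_clip_fraction * total_g
  fw <- rep(NA_real_, length(delta_grid))
  fw[ok] <- vapply(delta_grid[ok], mean_fwhm_at, 0)
  if (all(is.na(fw))) {
    warning("no candidate delta qualifies; falling back to delta = 2",
            call. = FALSE)
    return(2)
  }
  delta_grid[which.min(fw)]
}

#' Richardson-Lucy deconvolution
#'
#' Standard multiplicative iteration with circular FFT convolution.  With
#' zero iterations the input is returned unchanged; total intensity is
#' conserved to within the usual Richardson-Lucy tolerance.
#'
#' @param image An [intensity_image()] (or matrix).
#' @param psf Unit-sum non-negative PSF kernel ([intensity_image()] or
#'   matrix), e.g. the effective PSF of the imaging channel.
#' @param iterations Number of iterations (>= 0, default 10).
#' @return Deblurred image of the same type as `image`.
#' @export
deconvolve_rl <- function(image, psf, iterations = 10L) {
  iterations <- as.integer(iterations)
  if (iterations < 0L) stopf("iterations must be >= 0",
                             class = "phasorFSTM_parameter_error")
  v <- if (inherits(image, "intensity_image")) image$values else image
  k <- if (inherits(psf, "intensity_image")) psf$values else psf
  ks <- sum(k)
  if (ks <= 0) stopf("psf must have positive sum",
                     class = "phasorFSTM_parameter_error")
  if (abs(ks - 1) > 1e-6) k <- k / ks
  out <- v
  if (iterations > 0L) {
    otf <- psf_otf(k, dim(v))
    otf_t <- Conj(otf)
    est <- pmax(v, 0)
    if (all(est == 0)) est[] <- 0 else {
      eps <- 1e-12 * max(v)
      for (i in seq_len(iterations)) {
        den <- conv_circ(est, otf)
        ratio <- v / pmax(den, eps)
        est <- est * pmax(conv_circ(ratio, otf_t), 0)
      }
    }
    out <- est
  }
  if (inherits(image, "intensity_image"))
    intensity_image(pmax(out, 0), image$pixel_size_nm)
  else pmax(out, 0)
}

#' Default pseudo-color palette for the four-dye organelle set
#'
#' Mitochondrion yellow, microtubule green, lysosome magenta, nucleus cyan.
#'
#' @return Named character vector of colors.
#' @export
fstm_palette <- function() {
  c(mitochondrion = "yellow", microtubule = "green",
    lysosome = "magenta", nucleus = "cyan")
}

#' Compose per-dye images into a pseudo-color overlay
#'
#' Each dye image is normalised by its own maximum, tinted with its
#' assigned color, and the channels are added and clipped at 1.
#'
#' @param images Named list of [intensity_image()]s (or matrices), one per
#'   dye.
#' @param colors Named character vector (R color names or hex) mapping each
#'   dye to a color; defaults to [fstm_palette()] entries where names
#'   match.  Duplicated colors trigger a warning.
#' @param gamma Display gamma applied to each normalised channel before
#'   tinting (default 1 = off).
#' @return rows x cols x 3 numeric RGB array in `[0, 1]`.
#' @export
compose_multicolor <- function(images, colors = NULL, gamma = 1) {
  if (!length(images) || is.null(names(images)))
    stopf("images must be a non-empty named list",
          class = "phasorFSTM_parameter_error")
  if (is.null(colors)) {
    pal <- fstm_palette()
    colors <- vapply(seq_along(images), function(i) {
      nm <- names(images)[i]
      if (nm %in% names(pal)) pal[[nm]]
      else grDevices::rainbow(length(images))[i]
    }, "")
    names(colors) <- names(images)
  }
  if (anyDuplicated(colors))
    warning("duplicate colors assigned to different dyes", call. = FALSE)
  mats <- lapply(images, function(im)
    if (inherits(im, "intensity_image")) im$values else im)
  d <- dim(mats[[1L]])
  out <- array(0, dim = c(d[1L], d[2L], 3L))
  for (nm in names(mats)) {
    v <- mats[[nm]]
    if (!identical(dim(v), d))
      stopf("image shapes disagree", class = "phasorFSTM_parameter_error")
    mx <- max(v)
    ch <- if (mx > 0) (v / mx)^gamma else v * 0
    rgb <- grDevices::col2rgb(colors[[nm]])[, 1L] / 255
    for (c3 in 1:3) out[, , c3] <- out[, , c3] + ch * rgb[c3]
  }
  pmin(out, 1)
}
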