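# Simulation-backed validation harness: canonical study conditions used by
# the test-suite and the acceptance script.  The defaults ARE the study
# conditions (they are not tuning knobs): 23-nm beads behind a 0.40-lambda
# confocal channel, the four-dye organelle scene at a 35.26 photons/pixel
# operating point with a 59.31/40.69 Gaussian/donut photon split, delta = 2.

#' Effective phasor-FSTM point-spread function
#'
#' The subtraction channel's effective PSF: the Gaussian beam PSF minus
#' `delta` times the donut beam PSF (scaled by the donut/Gaussian power
#' ratio), clipped at zero.
#'
#' @param optics An [optics_config()].
#' @param delta Subtraction weight (default 2).
#' @param donut_power_ratio Donut-to-Gaussian detected-photon ratio
#'   (default 1, equal beams).
#' @param support_px Kernel support; defaults to [default_support_px()].
#' @param normalize Rescale to unit sum (default TRUE).
#' @return An [intensity_image()] kernel.
#' @export
effective_fstm_psf <- function(optics, delta = 2, donut_power_ratio = 1,
                               support_px = NULL, normalize = TRUE) {
  if (is.null(support_px)) support_px <- default_support_px(optics)
  g <- gaussian_psf(optics, support_px)$values
  d <- donut_psf(optics, support_px)$values
  eff <- pmax(g - delta * donut_power_ratio * d, 0)
  if (normalize && sum(eff) > 0) eff <- eff / sum(eff)
  intensity_image(eff, optics$pixel_size_nm)
}

#' FWHM of a centred kernel
#'
#' Mean of the horizontal and vertical profile FWHMs through the kernel
#' centre.
#'
#' @param kernel An [intensity_image()] with odd dimensions.
#' @return FWHM in nm (NA when undefined).
#' @export
kernel_fwhm <- function(kernel) {
  px <- kernel$pixel_size_nm
  nr <- nrow(kernel$values); nc <- ncol(kernel$values)
  cx <- nc / 2 * px; cy <- nr / 2 * px
  f <- c()
  for (ln in list(rbind(c(0, cy), c(nc * px, cy)),
                  rbind(c(cx, 0), c(cx, nr * px)))) {
    m <- measure_fwhm(kernel, ln, sampling_nm = px / 8)
    if (m$defined) f <- c(f, m$fwhm_nm)
  }
  if (!length(f)) NA_real_ else mean(f)
}

#' Photon-weighted phasor centroid
#'
#' @param field A `phasor_field`.
#' @return Named numeric `c(g, s)` over defined pixels, weighted by photon
#'   totals.
#' @export
phasor_centroid <- function(field) {
  w <- field$total[field$defined]
  c(g = sum(field$g[field$defined] * w) / sum(w),
    s = sum(field$s[field$defined] * w) / sum(w))
}

# Simulate a spatially uniform field of pure dye(s) and return the
# calibrated Gaussian-window phasor field.  `fractions` splits the
# per-pixel expected photons among the dyes (phasor mixing is linear in
# photon fractions).
uniform_mixture_field <- function(dyes, fractions, photons_per_pixel = 100,
                                  grid_px = 40L, timing = timing_config(),
                                  irf = irf_model(), tau_ref_ns = 3.8,
                                  seed = 1L, min_photons = 10) {
  dyes <- check_dyes(dyes)
  stopifnot(length(fractions) == length(dyes), abs(sum(fractions) - 1) < 1e-9)
  lam <- lapply(fractions, function(f)
    matrix(f * photons_per_pixel, grid_px, grid_px))
  names(lam) <- names(dyes)
  zero <- lapply(lam, function(m) m * 0)
  sim <- sample_stack(lam, zero, dyes, timing, irf, seed, pixel_size_nm = 40)
  sp <- split_stack(sim$stack, timing$donut_pulse_bin)
  field <- phasor_transform(sp$gaussian, min_photons = min_photons)
  ref <- simulate_reference_decay(tau_ref_ns, timing, irf, "gaussian",
                                  n_photons = 2e6,
                                  seed = substream_seed(seed, 97L, 1L))
  ref_win <- ref[seq_len(timing$donut_pulse_bin)]
  calibrate_phasor(field, ref_win, tau_ref_ns)$field
}

#' Universal-semicircle check for pure dyes
#'
#' Simulates a uniform field of each pure mono-exponential dye, calibrates
#' the Gaussian-window phasor field against a simulated lifetime standard,
#' and reports the distance of the photon-weighted centroid from the
#' universal semicircle (circle centred (0.5, 0), radius 0.5).
#'
#' @param tau_ns Vector of lifetimes to test (ns).
#' @param photons_per_pixel Expected photons per pixel (Gaussian beam).
#' @param grid_px Field side length in pixels.
#' @param timing,irf Acquisition configuration.
#' @param tau_ref_ns Calibration standard lifetime.
#' @param seed Integer seed.
#' @return data.frame with `tau_ns`, centroid `g`, `s`, and
#'   `semicircle_distance`.
#' @export
phasor_semicircle_check <- function(tau_ns = c(0.3, 1.0, 3.3, 3.8),
                                    photons_per_pixel = 100, grid_px = 40L,
                                    timing = timing_config(),
                                    irf = irf_model(), tau_ref_ns = 3.8,
                                    seed = 1L) {
  out <- lapply(seq_along(tau_ns), function(i) {
    dy <- list(dye_spec(paste0("tau", tau_ns[i]), tau_ns[i]))
    f <- uniform_mixture_field(dy, 1, photons_per_pixel, grid_px, timing,
                               irf, tau_ref_ns, seed = seed + i)
    ctr <- phasor_centroid(f)
    data.frame(tau_ns = tau_ns[i], g = ctr["g"], s = ctr["s"],
               semicircle_distance =
                 abs(sqrt((ctr["g"] - 0.5)^2 + ctr["s"]^2) - 0.5))
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Phasor linearity check for two-dye mixtures
#'
#' Pixels containing two dyes with photon fractions f and 1-f have an
#' expected phasor on the chord joining the pure-dye phasors.  Simulates
#' mixed uniform fields and reports the perpendicular distance of each
#' mixture centroid from the chord between the measured pure centroids.
#'
#' @param tau_pair Two lifetimes (ns).
#' @param fractions Photon fractions of the first dye to test.
#' @inheritParams phasor_semicircle_check
#' @return data.frame with `fraction` and `chord_deviation`.
#' @export
phasor_linearity_check <- function(tau_pair = c(1.0, 3.8),
                                   fractions = c(0.25, 0.5, 0.75),
                                   photons_per_pixel = 200, grid_px = 30L,
                                   timing = timing_config(),
                                   irf = irf_model(), tau_ref_ns = 3.8,
                                   seed = 1L) {
  dyes <- list(dye_spec("a", tau_pair[1L]), dye_spec("b", tau_pair[2L]))
  cent <- function(fr, sd_off) phasor_centroid(
    uniform_mixture_field(dyes, c(fr, 1 - fr), photons_per_pixel, grid_px,
                          timing, irf, tau_ref_ns, seed = seed + sd_off))
  z1 <- cent(1, 101L)
  z2 <- cent(0, 102L)
  u <- c(z2["g"] - z1["g"], z2["s"] - z1["s"])
  u <- u / sqrt(sum(u^2))
  perp <- c(-u[2L], u[1L])
  out <- lapply(seq_along(fractions), function(i) {
    zm <- cent(fractions[i], 200L + i)
    dev <- abs((zm["g"] - z1["g"]) * perp[1L] + (zm["s"] - z1["s"]) * perp[2L])
    data.frame(fraction = fractions[i], chord_deviation = dev)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Bead-field resolution benchmark
#'
#' Simulates a field of isolated 23-nm beads (single 3.8-ns dye, equal
#' beam powers), runs the full chain (demultiplex, calibrated phasor
#' gating, weighted subtraction at `delta`), and measures the mean FWHM of
#' horizontal and vertical profiles through every bead in both the
#' confocal (Gaussian) and phasor-FSTM images.
#'
#' @param seed Integer seed.
#' @param delta Subtraction weight (default 2).
#' @param n_beads_x,n_beads_y Bead grid dimensions (default 4 x 3 = 12
#'   beads, comfortably isolated at 1.28 um spacing).
#' @param photons_per_bead Expected photons per bead per beam (default
#'   20000: bright lifetime-standard beads, so profile shot noise is small
#'   relative to the width being measured).
#' @param pixel_size_nm Lateral sampling (default 20 nm).
#' @param optics Optical configuration; the default pins the confocal
#'   channel to FWHM 0.40 * lambda and the donut ring radius to 0.6 of it.
#' @return List with `mean_fwhm_nm`, `fwhm_frac_lambda`, per-profile
#'   widths, the confocal baseline, and the number of profiles.
#' @export
bead_resolution_benchmark <- function(seed = 1L, delta = 2,
                                      n_beads_x = 4L, n_beads_y = 3L,
                                      photons_per_bead = 20000,
                                      pixel_size_nm = 20,
                                      optics = NULL) {
  if (is.null(optics))
    optics <- optics_config(pixel_size_nm = pixel_size_nm)
  spacing <- 1280
  margin <- 640
  extent <- c(margin * 2 + (n_beads_x - 1L) * spacing,
              margin * 2 + (n_beads_y - 1L) * spacing)
  centers <- as.matrix(expand.grid(
    x = margin + (seq_len(n_beads_x) - 1L) * spacing,
    y = margin + (seq_len(n_beads_y) - 1L) * spacing))
  dyes <- list(lysosome = dye_spec("lysosome", 3.8, brightness = 1))
  structs <- lapply(seq_len(nrow(centers)), function(i)
    scene_bead(centers[i, ], diameter_nm = 23, dye = "lysosome",
               amplitude = photons_per_bead))
  sc <- scene(extent, structs)
  timing <- timing_config()
  irf <- irf_model()
  sim <- simulate_acquisition(sc, optics, dyes, timing, irf, seed = seed)
  b <- tryCatch(detect_boundary(sim$stack),
                error = function(e) timing$donut_pulse_bin)
  sp <- split_stack(sim$stack, b)
  fields <- lapply(sp, phasor_transform)
  ref <- simulate_reference_decay(3.8, timing, irf, "gaussian",
                                  n_photons = 2e6,
                                  seed = substream_seed(seed, 98L, 1L))
  refs <- list(gaussian = ref[seq_len(b)], donut = {
    rd <- simulate_reference_decay(3.8, timing, irf, "donut",
                                   n_photons = 2e6,
                                   seed = substream_seed(seed, 98L, 2L))
    rd[(b + 1L):timing$n_bins]
  })
  fields <- lapply(names(fields), function(nm)
    calibrate_phasor(fields[[nm]], refs[[nm]], 3.8)$field)
  names(fields) <- c("gaussian", "donut")
  fields <- lapply(fields, smooth_phasor)
  labels <- lapply(fields, function(f)
    assign_pixels(f, gates_from_lifetimes(dyes, f$omega, radius = 0.1)))
  comp <- extract_components(labels, sp$gaussian, sp$donut)
  ig <- comp$images$lysosome$gaussian
  id <- comp$images$lysosome$donut
  sr <- subtract_weighted(ig, id, delta)
  half_len <- 400
  profile_set <- function(img) {
    f <- numeric(0)
    for (i in seq_len(nrow(centers))) {
      cx <- centers[i, 1L]; cy <- centers[i, 2L]
      for (ln in list(rbind(c(cx - half_len, cy), c(cx + half_len, cy)),
                      rbind(c(cx, cy - half_len), c(cx, cy + half_len)))) {
        m <- measure_fwhm(img, ln, sampling_nm = pixel_size_nm / 4)
        if (m$defined) f <- c(f, m$fwhm_nm)
      }
    }
    f
  }
  f_sr <- profile_set(sr)
  f_conf <- profile_set(ig)
  list(mean_fwhm_nm = mean(f_sr),
       fwhm_frac_lambda = mean(f_sr) / optics$wavelength_nm,
       se_nm = stats::sd(f_sr) / sqrt(length(f_sr)),
       n_profiles = length(f_sr),
       per_profile_nm = f_sr,
       confocal_mean_fwhm_nm = mean(f_conf),
       confocal_frac_lambda = mean(f_conf) / optics$wavelength_nm,
       delta = delta, boundary_bin = b)
}

#' The four-dye organelle demonstration scene
#'
#' A 10.24 x 10.24 um cell-like layout: a filled nuclear disk (1.0 ns),
#' curved mitochondrial ribbons (0.3 ns), long thin microtubule filaments
#' (3.3 ns), and round lysosome beads (3.8 ns).  Structures are laid out
#' as spatially distinct organelles (neighbouring structures at least a
#' couple of PSF widths apart) with comparable per-pixel emitter density,
#' so that after normalisation to the reference operating point the
#' photon-count distribution resembles the reported acquisition: a bright
#' structure foreground over empty background with a per-pixel maximum
#' near 120 counts.
#'
#' @return A [scene()] over a 10240 x 10240 nm extent.
#' @export
fourcolor_scene <- function() {
  ext <- c(10240, 10240)
  dens <- 60  # emitter density per pixel, common to all structures
  structs <- list(
    # nucleus: filled disk, diameter 4.4 um (uniform density)
    scene_bead(c(2400, 2400), diameter_nm = 4400, dye = "nucleus",
               amplitude = dens * pi * 2200^2 / 40^2),
    # mitochondria: curved ribbons, 300 nm wide
    scene_filament(rbind(c(6600, 1600), c(7600, 3000), c(7000, 4600)),
                   width_nm = 300, dye = "mitochondrion", amplitude = dens),
    scene_filament(rbind(c(8400, 5600), c(9200, 7000), c(8600, 8400)),
                   width_nm = 300, dye = "mitochondrion", amplitude = dens),
    scene_filament(rbind(c(5600, 6000), c(6800, 7200), c(6400, 8000)),
                   width_nm = 300, dye = "mitochondrion", amplitude = dens),
    # microtubules: long thin filaments, 160 nm wide
    scene_filament(rbind(c(4400, 400), c(9800, 800)), width_nm = 160,
                   dye = "microtubule", amplitude = dens),
    scene_filament(rbind(c(400, 5000), c(4400, 5600), c(9800, 5000)),
                   width_nm = 160, dye = "microtubule", amplitude = dens),
    scene_filament(rbind(c(400, 9000), c(5000, 8600), c(9800, 9200)),
                   width_nm = 160, dye = "microtubule", amplitude = dens),
    scene_filament(rbind(c(400, 9800), c(5200, 9400), c(9800, 9800)),
                   width_nm = 160, dye = "microtubule", amplitude = dens)
  )
  lyso <- rbind(c(5200, 2000), c(5200, 3200), c(5600, 4000), c(1200, 6800),
                c(2000, 7600), c(3600, 6800), c(800, 7800), c(2800, 7600),
                c(9400, 2000), c(8800, 2600), c(7600, 6200), c(400, 600))
  for (i in seq_len(nrow(lyso)))
    structs <- c(structs, list(scene_bead(lyso[i, ], diameter_nm = 400,
                                          dye = "lysosome",
                                          amplitude = dens * pi * 200^2 / 40^2)))
  scene(ext, structs)
}

#' Four-color unmixing benchmark at the reference operating point
#'
#' Simulates the [fourcolor_scene()] with the four reference dyes at a mean
#' of 35.26 photons per pixel on a 256 x 256 grid, 59.31% of the photons
#' in the Gaussian channel and 40.69% in the donut channel, then runs the
#' full demultiplex / calibrate / smooth / gate chain and scores the
#' Gaussian-channel dye assignment against the ground-truth label map.
#'
#' Phasor coordinates are median-filtered (3 x 3, `smooth_passes` passes)
#' before gating; at a few tens of photons per pixel several passes are
#' needed to bring shot noise below the 3.3 / 3.8 ns gate separation.
#' Gates start at the theoretical semicircle positions and are then
#' recentred on the observed clusters with [refine_gates()], as when
#' extraction circles are placed on the visible phasor clusters; the gate
#' radius (default 0.2) covers roughly three pooled-shot-noise standard
#' deviations at the structure photon level.
#'
#' @param seed Integer seed.
#' @param mean_photons_per_pixel Image-average photon count (default 35.26).
#' @param gaussian_fraction Fraction of all photons in the Gaussian channel
#'   (default 0.5931).
#' @param smooth_kernel_px,smooth_passes Median-filter kernel size and
#'   passes on the phasor field (default 5 x 5, 3 passes): pooling over a
#'   few tens of pixels is what brings per-pixel shot noise at this photon
#'   level below the 3.3 / 3.8 ns cluster separation.
#' @param gate_radius Gate radius in phasor units (default 0.2).
#' @return List with `scores` (from [assignment_scores()]), the label
#'   maps, the component bookkeeping, and the simulation truth.
#' @export
fourcolor_benchmark <- function(seed = 1L, mean_photons_per_pixel = 35.26,
                                gaussian_fraction = 0.5931,
                                smooth_kernel_px = 5L, smooth_passes = 3L,
                                gate_radius = 0.2) {
  optics <- optics_config(pixel_size_nm = 40)
  timing <- timing_config()
  irf <- irf_model()
  dyes <- reference_dyes()
  sc <- fourcolor_scene()
  support <- default_support_px(optics)
  pg <- gaussian_psf(optics, support)
  pd <- donut_psf(optics, support)
  eg <- render_expected(sc, optics, pg, dyes, "gaussian")
  ed <- render_expected(sc, optics, pd, dyes, "donut")
  npix <- length(eg[[1L]])
  target_total <- mean_photons_per_pixel * npix
  sg <- gaussian_fraction * target_total / sum(Reduce(`+`, eg))
  sd_ <- (1 - gaussian_fraction) * target_total / sum(Reduce(`+`, ed))
  eg <- lapply(eg, `*`, sg)
  ed <- lapply(ed, `*`, sd_)
  sim <- sample_stack(eg, ed, dyes, timing, irf, seed,
                      pixel_size_nm = optics$pixel_size_nm)
  b <- tryCatch(detect_boundary(sim$stack),
                error = function(e) timing$donut_pulse_bin)
  sp <- split_stack(sim$stack, b)
  field <- phasor_transform(sp$gaussian)
  ref <- simulate_reference_decay(3.8, timing, irf, "gaussian",
                                  n_photons = 2e6,
                                  seed = substream_seed(seed, 99L, 1L))
  field <- calibrate_phasor(field, ref[seq_len(b)], 3.8)$field
  field <- smooth_phasor(field, kernel_px = smooth_kernel_px,
                         passes = smooth_passes)
  dye_order <- dyes[sim$truth$dye_names]
  gates <- suppressWarnings(
    gates_from_lifetimes(dye_order, field$omega, radius = gate_radius))
  gates <- refine_gates(field, gates)
  labels <- assign_pixels(field, gates)
  scores <- assignment_scores(labels, sim$truth$labels)
  comp <- extract_components(labels, sp$gaussian, sp$donut)
  list(scores = scores, labels = labels, truth = sim$truth,
       bookkeeping = comp$bookkeeping, boundary_bin = b,
       stack_total = sum(sim$stack$counts),
       mean_photons_per_pixel = sum(sim$stack$counts) / npix)
}
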