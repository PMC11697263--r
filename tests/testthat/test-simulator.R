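optics <- optics_config(pixel_size_nm = 40)

test_that("gaussian PSF has the configured width, symmetry, and unit sum", {
  k <- gaussian_psf(optics, 31L)
  expect_equal(sum(k$values), 1, tolerance = 1e-9)
  expect_identical(k$values, k$values[31:1, 31:1])          # 180 deg rotation
  expect_equal(arrayInd(which.max(k$values), c(31L, 31L)),
               matrix(c(16L, 16L), 1L))                     # max at centre
  expect_equal(kernel_fwhm(k), optics$gaussian_fwhm_nm,
               tolerance = optics$pixel_size_nm / 2 / optics$gaussian_fwhm_nm)
  expect_error(gaussian_psf(optics, 5L), class = "phasorFSTM_truncation_error")
})

test_that("donut PSF is zero-centred with its ring at the configured radius", {
  k <- donut_psf(optics, 31L)
  expect_equal(sum(k$values), 1, tolerance = 1e-9)
  expect_identical(k$values[16, 16], 0)
  expect_equal(k$values, t(k$values[31:1, ]), tolerance = 1e-12)  # 90 deg rotation
  # argmax radius
  idx <- which(k$values == max(k$values), arr.ind = TRUE)[1, ]
  r <- sqrt(sum(((idx - 16) * optics$pixel_size_nm)^2))
  expect_lt(abs(r - optics$donut_peak_radius_nm), optics$pixel_size_nm / 2 + 1e-9)
})

test_that("render_expected conserves mass and is linear/additive", {
  dyes <- list(a = dye_spec("a", 1.0, brightness = 1))
  psf <- gaussian_psf(optics, 31L)
  sc1 <- scene(c(4000, 4000), list(
    scene_bead(c(2000, 2000), 23, "a", amplitude = 100)))
  m1 <- render_expected(sc1, optics, psf, dyes)
  expect_equal(sum(m1$a), 100, tolerance = 1e-6)
  # bead centred on a pixel: peak at the bead's pixel
  expect_equal(which.max(m1$a), which.max(rasterize_scene(sc1, 40)$a))

  sc2 <- scene(c(4000, 4000), list(
    scene_bead(c(1000, 1000), 23, "a", amplitude = 50)))
  m2 <- render_expected(sc2, optics, psf, dyes)
  sc12 <- scene(c(4000, 4000), c(sc1$structures, sc2$structures))
  m12 <- render_expected(sc12, optics, psf, dyes)
  expect_equal(m12$a, m1$a + m2$a, tolerance = 1e-12)

  # amplitude linearity
  sc1b <- scene(c(4000, 4000), list(
    scene_bead(c(2000, 2000), 23, "a", amplitude = 300)))
  expect_equal(render_expected(sc1b, optics, psf, dyes)$a, 3 * m1$a,
               tolerance = 1e-12)

  # empty scene gives zero maps
  expect_length(render_expected(scene(c(4000, 4000)), optics, psf, dyes), 0L)
})

test_that("sample_stack is deterministic, conserves Poisson means, and partitions beams", {
  tm <- timing_config()
  dyes <- list(d = dye_spec("d", 3.8))
  lam <- list(d = matrix(50, 10, 10))
  zero <- list(d = matrix(0, 10, 10))

  out0 <- sample_stack(zero, zero, dyes, tm, irf_model(), seed = 1)
  expect_identical(sum(out0$stack$counts), 0L)

  out1 <- sample_stack(lam, lam, dyes, tm, irf_model(), seed = 1)
  out1b <- sample_stack(lam, lam, dyes, tm, irf_model(), seed = 1)
  expect_identical(out1$stack$counts, out1b$stack$counts)

  expected_total <- 2 * sum(lam$d)
  expect_lt(abs(sum(out1$stack$counts) - expected_total),
            4 * sqrt(expected_total))

  # uniform dark counts add on top and roughly match their expectation
  outb <- sample_stack(lam, lam, dyes, tm, irf_model(), seed = 1,
                       background = 5)
  extra <- sum(outb$stack$counts) - sum(out1$stack$counts)
  expect_lt(abs(extra - 500), 4 * sqrt(500))

  # Gaussian-beam leakage past the boundary is reported and bounded
  leak <- out1$truth$gaussian_leakage_fraction["d"]
  bound <- exp(-(tm$donut_pulse_bin - tm$gaussian_pulse_bin) *
                 tm$bin_width_ns / 3.8) + 0.02
  expect_lt(leak, bound)
  expect_gt(leak, 0)
})

test_that("adding a dye does not perturb existing dyes' draws", {
  tm <- timing_config()
  one <- list(d1 = dye_spec("d1", 1.0))
  two <- list(d1 = dye_spec("d1", 1.0), d2 = dye_spec("d2", 3.3))
  lam1 <- list(d1 = matrix(30, 6, 6))
  lam2 <- list(d1 = matrix(30, 6, 6), d2 = matrix(0, 6, 6))
  a <- sample_stack(lam1, lam1, one, tm, irf_model(), seed = 11)
  b <- sample_stack(lam2, lam2, two, tm, irf_model(), seed = 11)
  expect_identical(a$stack$counts, b$stack$counts)
})

test_that("empirical arrival-time distribution matches the IRF-convolved decay", {
  tm <- timing_config()
  irf <- irf_model(sigma_ns = 0.10)
  tau <- 2.0
  h <- simulate_reference_decay(tau, tm, irf, "gaussian",
                                n_photons = 1e5, seed = 21)
  n <- sum(h)
  edges <- seq_len(tm$n_bins) * tm$bin_width_ns
  t0 <- (tm$gaussian_pulse_bin + 0.5) * tm$bin_width_ns
  model <- wrapped_emg_cdf(edges, t0, tau, irf$sigma_ns, tm$period_ns)
  ks <- max(abs(cumsum(h) / n - model))
  expect_lt(ks, 0.01)
})

test_that("simulate_acquisition is reproducible and scales with brightness", {
  sc <- scene(c(2000, 2000), list(
    scene_bead(c(1000, 1000), 23, "d", amplitude = 500)))
  tm <- timing_config()
  d1 <- list(d = dye_spec("d", 1.0, brightness = 1))
  d2 <- list(d = dye_spec("d", 1.0, brightness = 2))
  op <- optics_config(pixel_size_nm = 40)
  a <- simulate_acquisition(sc, op, d1, tm, seed = 2)
  a2 <- simulate_acquisition(sc, op, d1, tm, seed = 2)
  expect_identical(a$stack$counts, a2$stack$counts)
  b <- simulate_acquisition(sc, op, d2, tm, seed = 2)
  expect_equal(sum(Reduce(`+`, b$truth$expected_gaussian)),
               2 * sum(Reduce(`+`, a$truth$expected_gaussian)),
               tolerance = 1e-9)
})
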