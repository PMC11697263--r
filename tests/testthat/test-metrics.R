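test_that("FWHM of an analytic Gaussian equals 2.3548 sigma anywhere", {
  for (ctr in list(c(505, 505), c(303, 707))) {
    img <- gaussian_spot_image(sigma_nm = 50, pixel_size_nm = 10,
                               center_nm = ctr)
    ln <- rbind(c(ctr[1] - 300, ctr[2]), c(ctr[1] + 300, ctr[2]))
    m <- measure_fwhm(img, ln)
    expect_true(m$defined)
    expect_equal(m$fwhm_nm, 2 * sqrt(2 * log(2)) * 50, tolerance = 1 / 117)
  }
  # flat image: no half-maximum crossing
  flat <- intensity_image(matrix(1, 50, 50), 10)
  mf <- measure_fwhm(flat, rbind(c(50, 250), c(450, 250)))
  expect_false(mf$defined)
  expect_true(is.na(mf$fwhm_nm))
})

test_that("a near-point source through the confocal channel reports the PSF width", {
  op <- optics_config(pixel_size_nm = 20)
  dyes <- list(d = dye_spec("d", 1.0))
  sc <- scene(c(2560, 2560), list(scene_bead(c(1280, 1280), 23, "d", 3e4)))
  sim <- simulate_acquisition(sc, op, dyes, timing_config(), seed = 61)
  sp <- split_stack(sim$stack, 128L)   # confocal channel only
  img <- intensity_image(pixel_totals(sp$gaussian), 20)
  m <- measure_fwhm(img, rbind(c(880, 1280), c(1680, 1280)))
  expect_lt(abs(m$fwhm_nm - op$gaussian_fwhm_nm) / op$gaussian_fwhm_nm, 0.05)
})

test_that("mean_fwhm averages defined profiles and excludes undefined ones", {
  img <- gaussian_spot_image(sigma_nm = 50, pixel_size_nm = 10)
  ctr <- c(505, 505)
  ln <- rbind(c(ctr[1] - 300, ctr[2]), c(ctr[1] + 300, ctr[2]))
  five <- rep(list(ln), 5)
  r <- mean_fwhm(img, five)
  expect_equal(r$se_nm, 0)
  expect_equal(r$n, 5L)

  # an off-structure line is undefined and gets excluded
  off <- rbind(c(20, 20), c(220, 20))
  r2 <- mean_fwhm(img, c(five, list(off)))
  expect_equal(r2$n, 5L)
  expect_equal(r2$n_excluded, 1L)
  expect_error(mean_fwhm(img, list(off, off)),
               class = "phasorFSTM_measurement_error")
})

test_that("SBR is the ratio of mask means with declared edge cases", {
  v <- matrix(1, 10, 10); v[1:3, ] <- 8
  sig <- matrix(FALSE, 10, 10); sig[1:3, ] <- TRUE
  bg <- !sig
  expect_equal(compute_sbr(v, sig, bg), 8)
  mA <- matrix(FALSE, 4, 4); mA[1, ] <- TRUE
  mB <- matrix(FALSE, 4, 4); mB[2, ] <- TRUE
  expect_equal(compute_sbr(matrix(5, 4, 4), mA, mB), 1)
  v0 <- matrix(0, 4, 4); v0[1, 1] <- 3
  m1 <- matrix(FALSE, 4, 4); m1[1, 1] <- TRUE
  m2 <- matrix(FALSE, 4, 4); m2[4, 4] <- TRUE
  expect_identical(compute_sbr(v0, m1, m2), Inf)
  expect_error(compute_sbr(v, sig, sig), class = "phasorFSTM_parameter_error")
  expect_error(compute_sbr(v, sig, matrix(FALSE, 10, 10)),
               class = "phasorFSTM_parameter_error")
})

test_that("assignment scores have the standard confusion-matrix semantics", {
  tr <- matrix(c(1, 1, 2, 2, 0, 0), 2, 3)
  expect_equal(assignment_scores(tr, tr)$macro_f1, 1)
  pred0 <- matrix(0L, 2, 3)
  s0 <- assignment_scores(pred0, tr)
  expect_true(all(s0$per_class$recall == 0))
  expect_equal(s0$macro_f1, 0)
  # truth-0 pixels are excluded: predictions there change nothing
  pred <- tr; pred[tr == 0] <- 2L
  expect_equal(assignment_scores(pred, tr)$macro_f1, 1)
  expect_error(assignment_scores(pred0, matrix(0L, 2, 3)),
               class = "phasorFSTM_measurement_error")
})
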