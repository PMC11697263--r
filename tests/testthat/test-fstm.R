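test_that("weighted subtraction follows the clipped formula exactly", {
  ig <- matrix(c(4, 2, 8, 1), 2, 2)  # [[4,8],[2,1]] in row-major reading
  id <- matrix(c(1, 2, 2, 0), 2, 2)
  out <- subtract_weighted(ig, id, 2)
  expect_identical(out, matrix(c(2, 0, 4, 1), 2, 2))
  expect_identical(subtract_weighted(ig, id, 0), ig)
  expect_identical(subtract_weighted(ig, matrix(0, 2, 2), 5), ig)
  expect_error(subtract_weighted(ig, matrix(0, 3, 3), 1),
               class = "phasorFSTM_parameter_error")
  expect_error(subtract_weighted(ig, id, -1),
               class = "phasorFSTM_parameter_error")
})

test_that("subtraction is dominated by i_g and monotone in delta (loop oracle)", {
  set.seed(19)
  ig <- matrix(runif(400, 0, 10), 20, 20)
  id <- matrix(runif(400, 0, 5), 20, 20)
  prev <- NULL
  for (delta in c(0, 0.5, 1, 2)) {
    out <- subtract_weighted(ig, id, delta)
    # explicit per-pixel loop oracle
    oracle <- matrix(0, 20, 20)
    for (r in 1:20) for (c in 1:20)
      oracle[r, c] <- max(ig[r, c] - delta * id[r, c], 0)
    expect_identical(out, oracle)
    expect_true(all(out <= ig + 1e-15))
    if (!is.null(prev)) expect_true(all(out <= prev + 1e-15))
    prev <- out
  }
})

test_that("auto_delta honours its grid, fallback, and narrowing contract", {
  expect_identical(suppressWarnings(
    auto_delta(matrix(1, 5, 5), matrix(1, 5, 5), delta_grid = 2)), 2)
  expect_warning(flat <- auto_delta(matrix(0, 9, 9), matrix(0, 9, 9)),
                 "no bright spots")
  expect_identical(flat, 2)

  op <- optics_config(pixel_size_nm = 20)
  k <- default_support_px(op)
  ig <- gaussian_psf(op, k)
  id <- donut_psf(op, k)
  sel <- suppressWarnings(auto_delta(ig, id, delta_grid = c(0, 1, 2)))
  f_sel <- kernel_fwhm(intensity_image(pmax(ig$values - sel * id$values, 0), 20))
  f_0 <- kernel_fwhm(ig)
  expect_lte(f_sel, f_0)
})

test_that("Richardson-Lucy deconvolution sharpens while conserving intensity", {
  op <- optics_config(pixel_size_nm = 20)
  sup <- default_support_px(op)
  psf <- gaussian_psf(op, sup)
  # blurred point source on a 101 x 101 canvas
  img <- matrix(0, 101, 101); img[51, 51] <- 1000
  blurred <- pmax(EBImage::filter2(img, psf$values, boundary = 0), 0)
  bi <- intensity_image(blurred, 20)

  expect_identical(deconvolve_rl(bi, psf, 0L)$values, bi$values)

  delta_psf <- matrix(0, 3, 3); delta_psf[2, 2] <- 1
  expect_equal(deconvolve_rl(bi, delta_psf, 7L)$values, bi$values,
               tolerance = 1e-9)

  dec <- deconvolve_rl(bi, psf, 10L)
  expect_lt(kernel_fwhm(dec), kernel_fwhm(bi))
  expect_equal(sum(dec$values), sum(bi$values), tolerance = 0.01)
  expect_true(all(dec$values >= 0))

  expect_error(deconvolve_rl(bi, matrix(0, 3, 3), 1L),
               class = "phasorFSTM_parameter_error")
})

test_that("multicolor composition tints, superimposes, and clips", {
  a <- matrix(0, 4, 4); a[1:2, ] <- 3
  b <- matrix(0, 4, 4); b[4, ] <- 7
  rgbimg <- compose_multicolor(list(x = a, y = b),
                               colors = c(x = "red", y = "green"))
  expect_equal(dim(rgbimg), c(4, 4, 3))
  expect_equal(rgbimg[1, 1, ], c(1, 0, 0))
  expect_equal(rgbimg[4, 1, ], c(0, 1, 0))
  expect_equal(max(rgbimg[3, , ]), 0)  # disjoint supports never mix

  # single dye in white is a grayscale rendering
  w <- compose_multicolor(list(x = a), colors = c(x = "white"))
  expect_equal(w[, , 1], a / max(a))
  expect_equal(w[, , 1], w[, , 2])

  expect_warning(compose_multicolor(list(x = a, y = b),
                                    colors = c(x = "red", y = "red")),
                 "duplicate")
  # the four-dye palette is available for the organelle set
  expect_setequal(names(fstm_palette()),
                  c("mitochondrion", "microtubule", "lysosome", "nucleus"))
})
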