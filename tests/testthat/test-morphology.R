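raster_disk <- function(radius_px, pad = 2L) {
  n <- 2L * (radius_px + pad) + 1L
  ctr <- radius_px + pad + 1L
  outer(seq_len(n), seq_len(n),
        function(r, c) (r - ctr)^2 + (c - ctr)^2 <= radius_px^2) * 1L
}

test_that("adaptive thresholding identifies objects and is monotone in offset", {
  expect_equal(max(identify_objects(matrix(0, 40, 40))), 0L)

  img <- matrix(0, 60, 90)
  img[15:25, 15:25] <- 5
  img[35:50, 55:75] <- 7
  lab <- identify_objects(img, window_px = 31L, offset = 0, min_area_px = 9L)
  expect_equal(max(lab), 2L)

  # a rasterised disk's recovered area is close to pi r^2
  disk <- raster_disk(10L, pad = 25L) * 10
  labd <- identify_objects(disk, window_px = 41L, offset = 0.5)
  expect_equal(max(labd), 1L)
  expect_lt(abs(sum(labd > 0) - 100 * pi) / (100 * pi), 0.05)

  # raising the offset never increases the object count
  counts <- vapply(c(0, 1, 3, 6, 8), function(off)
    max(identify_objects(img, offset = off)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("Crofton perimeter reproduces the reference estimator", {
  # frozen oracle: scikit-image perimeter_crofton(directions = 4) on the
  # same seed-42 random 20 x 20 mask gives 262.97924156...
  set.seed(42)
  m <- matrix(rbinom(400, 1, 0.4), 20, 20)
  expect_equal(phasorFSTM:::crofton_perimeter(m), 262.9792415608089,
               tolerance = 1e-12)
  # disk of radius 20: close to 2 pi r
  expect_lt(abs(phasorFSTM:::crofton_perimeter(raster_disk(20L)) -
                  2 * pi * 20) / (2 * pi * 20), 0.03)
})

test_that("morphology report: disk FF near 1, rectangle elongated", {
  disk <- raster_disk(20L)
  repd <- morphology_report(phasorFSTM:::label_components(disk), 1000,
                            include_skeleton = FALSE)
  expect_equal(repd$n_objects, 1L)
  ff_disk <- repd$objects$form_factor
  expect_gte(ff_disk, 0.9)
  expect_lte(ff_disk, 1.15)

  rect <- matrix(0L, 20, 70)
  rect[8:12, 11:60] <- 1L  # 5 x 50 bar
  repr <- morphology_report(phasorFSTM:::label_components(rect), 1000,
                            include_skeleton = FALSE)
  expect_lt(abs(repr$objects$aspect_ratio - 10) / 10, 0.1)
  # elongated objects have a larger form factor than round ones
  expect_gt(repr$objects$form_factor, ff_disk)
  # areas are converted to um^2 (1000 nm pixels -> 1 um^2 per pixel)
  expect_equal(repd$objects$area_um2, sum(disk))
})

test_that("skeleton stats count branches and junctions by their definitions", {
  bar <- matrix(0L, 9, 40); bar[5, 4:36] <- 1L
  sb <- skeleton_stats(bar)
  expect_equal(sb$branches, 1L)
  expect_equal(sb$junctions, 0L)

  # "Y": three bars meeting at one point
  y <- matrix(0L, 31, 31)
  y[16:30, 16] <- 1L
  for (k in 0:14) { y[15 - k, 16 - k] <- 1L; y[15 - k, 16 + k] <- 1L }
  sy <- skeleton_stats(y)
  expect_equal(sy$branches, 3L)
  expect_equal(sy$junctions, 1L)

  # "X": four bars, one (possibly clustered) junction
  x <- matrix(0L, 31, 31)
  for (k in -15:15) { x[16 + k, 16 + k] <- 1L; x[16 + k, 16 - k] <- 1L }
  sx <- skeleton_stats(x)
  expect_equal(sx$branches, 4L)
  expect_equal(sx$junctions, 1L)

  expect_error(skeleton_stats(matrix(0L, 5, 5)),
               class = "phasorFSTM_parameter_error")
})
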