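make_field <- function(g, s, total = matrix(100, nrow(g), ncol(g))) {
  structure(list(g = g, s = s, total = total,
                 defined = !is.na(g), omega = 2 * pi / 12.5, harmonic = 1L,
                 min_photons = 10, window_len = 128L,
                 bin_width_ns = 25 / 256, beam_label = "gaussian",
                 pixel_size_nm = 40, calibrated = TRUE),
            class = "phasor_field")
}

test_that("gates are built at the closed-form semicircle centres", {
  om <- 2 * pi / 12.5
  dyes <- reference_dyes()
  gates <- suppressWarnings(gates_from_lifetimes(dyes, om, radius = 0.1))
  expect_length(gates, 4L)
  th <- theoretical_phasor(c(0.3, 1.0, 3.3, 3.8), om)
  for (i in 1:4) expect_equal(gates[[i]]$center, unname(th[i, ]),
                              tolerance = 1e-12)
  # the 3.3 / 3.8 ns pair is closer than 2 * radius: overlap is warned
  expect_warning(gates_from_lifetimes(dyes, om, radius = 0.1), "overlap")

  expect_silent(gates_from_lifetimes(dyes["nucleus"], om, radius = 0.1))
  dup <- list(a = dye_spec("a", 1), b = dye_spec("b", 1))
  expect_error(gates_from_lifetimes(dup, om),
               class = "phasorFSTM_parameter_error")
})

test_that("pixel assignment follows containment, nearest centre, then index", {
  gates <- list(phasor_gate("a", c(0.25, 0.25), 0.3),
                phasor_gate("b", c(0.75, 0.25), 0.3))
  g <- matrix(c(0.25, 0.75, 0.5, 0.9, NA), 1)   # 0.5 is exactly equidistant
  s <- matrix(c(0.25, 0.25, 0.25, 0.9, 0.25), 1)
  lab <- assign_pixels(make_field(g, s), gates)
  expect_identical(as.integer(lab), c(1L, 2L, 1L, 0L, 0L))
  # pixel 3 is equidistant and inside both circles: lower index wins
  expect_identical(attr(lab, "labels"), c("a", "b"))
})

test_that("gate refinement recentres on clusters without collapsing overlaps", {
  set.seed(77)
  n <- 400L
  g <- matrix(c(rnorm(n, 0.30, 0.02), rnorm(n, 0.38, 0.02)), 2L * n, 1L)
  s <- matrix(c(rnorm(n, 0.40, 0.02), rnorm(n, 0.44, 0.02)), 2L * n, 1L)
  f <- make_field(g, s)
  gates <- list(phasor_gate("a", c(0.28, 0.39), 0.2),
                phasor_gate("b", c(0.40, 0.45), 0.2))
  ref <- refine_gates(f, gates)
  expect_lt(sqrt(sum((ref[[1]]$center - c(0.30, 0.40))^2)), 0.02)
  expect_lt(sqrt(sum((ref[[2]]$center - c(0.38, 0.44))^2)), 0.02)
  # overlapping circles keep distinct centres
  expect_gt(sqrt(sum((ref[[1]]$center - ref[[2]]$center)^2)), 0.05)
})

test_that("component extraction obeys exact photon bookkeeping", {
  st <- random_stack(seed = 23, n_bins = 32L)
  sp <- split_stack(st, st$timing$donut_pulse_bin)
  lab <- matrix(sample(0:2, 64, replace = TRUE), 8, 8)
  attr(lab, "labels") <- c("a", "b")
  comp <- extract_components(lab, sp$gaussian, sp$donut)
  bk <- comp$bookkeeping
  expect_identical(sum(bk$assigned[, "gaussian"]) + bk$unassigned[["gaussian"]],
                   sum(pixel_totals(sp$gaussian)) + 0)
  expect_identical(sum(bk$assigned[, "donut"]) + bk$unassigned[["donut"]],
                   sum(pixel_totals(sp$donut)) + 0)
  expect_identical(bk$total, sum(st$counts) + 0)
  # images are the per-pixel window totals on their label support
  expect_equal(comp$images$a$gaussian$values,
               pixel_totals(sp$gaussian) * (lab == 1))

  # all pixels unassigned -> zero images
  lab0 <- matrix(0L, 8, 8); attr(lab0, "labels") <- c("a", "b")
  comp0 <- extract_components(lab0, sp$gaussian, sp$donut)
  expect_identical(sum(comp0$images$a$gaussian$values), 0)
  expect_identical(unname(comp0$bookkeeping$unassigned[["gaussian"]]),
                   sum(pixel_totals(sp$gaussian)) + 0)
})

test_that("two pure regions separate into their own component images", {
  tm <- timing_config()
  dyes <- list(short = dye_spec("short", 0.3), long = dye_spec("long", 3.8))
  lam_a <- matrix(0, 16, 16); lam_a[, 1:8] <- 120
  lam_b <- matrix(0, 16, 16); lam_b[, 9:16] <- 120
  lam <- list(short = lam_a, long = lam_b)
  out <- sample_stack(lam, lam, dyes, tm, irf_model(), seed = 71)
  sp <- split_stack(out$stack, tm$donut_pulse_bin)
  f <- phasor_transform(sp$gaussian)
  ref <- simulate_reference_decay(3.8, tm, irf_model(), "gaussian",
                                  n_photons = 1e6, seed = 72)
  f <- calibrate_phasor(f, ref[seq_len(tm$donut_pulse_bin)], 3.8)$field
  f <- smooth_phasor(f)
  gates <- gates_from_lifetimes(dyes, f$omega, radius = 0.15)
  lab <- assign_pixels(f, gates)
  comp <- extract_components(lab, sp$gaussian, sp$donut)
  expect_identical(sum(comp$images$short$gaussian$values[, 9:16]), 0)
  expect_identical(sum(comp$images$long$gaussian$values[, 1:8]), 0)
  expect_gt(sum(comp$images$short$gaussian$values[, 1:8]), 0)
  expect_gt(sum(comp$images$long$gaussian$values[, 9:16]), 0)
  # assignment against the ground-truth labels is essentially perfect here
  sc <- assignment_scores(lab, out$truth$labels)
  expect_gt(sc$macro_f1, 0.99)
})
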