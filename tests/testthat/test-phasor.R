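test_that("phasor transform matches its closed-form special cases", {
  dt <- 25 / 256
  # all photons in bin 0
  cnt <- array(0L, c(1, 1, 8)); cnt[1, 1, 1] <- 5L
  d <- decay_stack(cnt, 0L, dt, "gaussian", 40)
  f <- phasor_transform(d, min_photons = 1)
  om <- 2 * pi / (8 * dt)
  expect_equal(f$g[1, 1], cos(om * dt / 2), tolerance = 1e-12)
  expect_equal(f$s[1, 1], sin(om * dt / 2), tolerance = 1e-12)
  expect_equal(f$omega, om)

  # uniform counts across the window sum to zero at the first harmonic
  d2 <- decay_stack(array(3L, c(1, 1, 16)), 0L, dt, "gaussian", 40)
  f2 <- phasor_transform(d2, min_photons = 1)
  expect_equal(f2$g[1, 1], 0, tolerance = 1e-12)
  expect_equal(f2$s[1, 1], 0, tolerance = 1e-12)

  # sampled mono-exponential with omega * tau = 1 lands at (0.5, 0.5)
  tm <- timing_config(period_ns = 12.5, n_bins = 128L,
                      gaussian_pulse_bin = 0L, donut_pulse_bin = 64L)
  tau <- 1 / (2 * pi / 12.5)  # 1.9894 ns
  h <- simulate_reference_decay(tau, tm, irf_model(0, 0), "gaussian",
                                n_photons = 2e5, seed = 1)
  # whole-period window, pulse at bin 0
  dfull <- decay_stack(array(as.integer(h), c(1, 1, 128)), 0L,
                       tm$bin_width_ns, "gaussian", 40)
  ff <- phasor_transform(dfull, min_photons = 1)
  # remove the half-bin pulse-position phase analytically
  z <- complex(real = ff$g[1, 1], imaginary = ff$s[1, 1]) *
    exp(-1i * ff$omega * 0.5 * tm$bin_width_ns)
  expect_lt(abs(z - complex(real = 0.5, imaginary = 0.5)), 0.01)
})

test_that("vectorised phasor transform equals the per-pixel loop oracle", {
  set.seed(13)
  for (rep in 1:5) {
    cnt <- array(rpois(2 * 2 * 8, 4), c(2, 2, 8))
    d <- decay_stack(cnt, 0L, 0.1, "gaussian", 40)
    f <- phasor_transform(d, min_photons = 0)
    o <- phasor_loop_oracle(d)
    expect_equal(f$g, o$g, tolerance = 1e-12)
    expect_equal(f$s, o$s, tolerance = 1e-12)
  }
})

test_that("theoretical phasor lies on the universal semicircle", {
  om <- 2 * pi / 12.5
  expect_equal(unname(theoretical_phasor(0, om)), cbind(1, 0),
               ignore_attr = TRUE)
  tau1 <- 1 / om
  expect_equal(unname(theoretical_phasor(tau1, om)[1, ]), c(0.5, 0.5),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_lt(sum(abs(theoretical_phasor(1e6 / om, om))), 1e-5)
  # all points on circle centred (0.5, 0), radius 0.5
  taus <- seq(0, 50, by = 0.37)
  th <- theoretical_phasor(taus, om)
  expect_equal(sqrt((th[, "g"] - 0.5)^2 + th[, "s"]^2),
               rep(0.5, length(taus)), tolerance = 1e-12)
  # monotonicity along the semicircle: g strictly decreasing, s unimodal
  expect_true(all(diff(th[-1, "g"]) < 0))
  s <- th[, "s"]
  pk <- which.max(s)
  expect_true(all(diff(s[seq_len(pk)]) >= 0))
  expect_true(all(diff(s[pk:length(s)]) <= 0))
})

test_that("calibration maps the reference exactly onto its theoretical point", {
  tm <- timing_config()
  irf <- irf_model()
  ref <- simulate_reference_decay(3.8, tm, irf, "gaussian",
                                  n_photons = 1e6, seed = 41)
  win <- ref[seq_len(tm$donut_pulse_bin)]
  dyes <- list(d = dye_spec("d", 1.0))
  lam <- list(d = matrix(100, 12, 12))
  zero <- list(d = matrix(0, 12, 12))
  out <- sample_stack(lam, zero, dyes, tm, irf, seed = 42)
  sp <- split_stack(out$stack, tm$donut_pulse_bin)
  f <- phasor_transform(sp$gaussian)
  cal <- calibrate_phasor(f, win, 3.8)
  # reference phasor under the returned correction equals theory exactly
  t_k <- (seq_along(win) - 0.5) * f$bin_width_ns
  zm <- complex(real = sum(win * cos(f$omega * t_k)) / sum(win),
                imaginary = sum(win * sin(f$omega * t_k)) / sum(win))
  corr <- complex(modulus = cal$record$modulation_correction,
                  argument = cal$record$phase_correction)
  th <- theoretical_phasor(3.8, f$omega)
  expect_equal(Re(zm * corr), as.numeric(th[1, "g"]), tolerance = 1e-12)
  expect_equal(Im(zm * corr), as.numeric(th[1, "s"]), tolerance = 1e-12)
  # a calibrated simulated dye sits on the semicircle
  ctr <- phasor_centroid(cal$field)
  expect_lt(abs(sqrt((ctr["g"] - 0.5)^2 + ctr["s"]^2) - 0.5), 0.02)

  expect_error(calibrate_phasor(f, rep(0, tm$donut_pulse_bin), 3.8),
               class = "phasorFSTM_calibration_error")
})

test_that("median smoothing is an identity for kernel 1 and fixes outliers", {
  f0 <- structure(list(g = matrix(0.4, 5, 5), s = matrix(0.3, 5, 5),
                       total = matrix(100, 5, 5),
                       defined = matrix(TRUE, 5, 5),
                       omega = 0.5, harmonic = 1L, min_photons = 10,
                       window_len = 10L, bin_width_ns = 0.1,
                       beam_label = "gaussian", pixel_size_nm = 40,
                       calibrated = FALSE), class = "phasor_field")
  expect_equal(smooth_phasor(f0, 1L, 1L)$g, f0$g)
  expect_equal(smooth_phasor(f0, 3L, 2L)$g, f0$g)  # constant is unchanged
  f1 <- f0
  f1$g[3, 3] <- 0.9
  sm <- smooth_phasor(f1, 3L, 1L)
  expect_equal(sm$g[3, 3], 0.4)
  expect_equal(sm$total, f0$total)  # totals untouched
  # undefined pixels stay undefined and do not contaminate neighbours
  f2 <- f0
  f2$g[2, 2] <- NA_real_; f2$defined[2, 2] <- FALSE
  sm2 <- smooth_phasor(f2, 3L, 1L)
  expect_true(is.na(sm2$g[2, 2]))
  expect_equal(sm2$g[2, 3], 0.4)
})

test_that("mono-exponential fitting recovers exact and simulated lifetimes", {
  dt <- 0.1
  tt <- (0:99 + 0.5) * dt
  exact <- 1000 * exp(-tt / 2)
  expect_equal(fit_monoexp(exact, dt, 0L), 2, tolerance = 1e-6)

  expect_error(fit_monoexp(rep(5, 50), dt, 0L), class = "phasorFSTM_fit_error")
  expect_error(fit_monoexp(c(0, 0, 1, 0), dt, 0L),
               class = "phasorFSTM_fit_error")

  tm <- timing_config()
  h <- simulate_reference_decay(3.8, tm, irf_model(), "gaussian",
                                n_photons = 1e4, seed = 51)
  start <- tm$gaussian_pulse_bin +
    as.integer(ceiling(3 * 0.1 / tm$bin_width_ns)) + 1L
  tau_hat <- fit_monoexp(h[seq_len(tm$donut_pulse_bin)], tm$bin_width_ns,
                         start)
  expect_lt(abs(tau_hat - 3.8) / 3.8, 0.05)
})
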