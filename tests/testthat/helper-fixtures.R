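# Shared fixture builders (everything is generated in code).

random_stack <- function(seed = 1L, nr = 8L, nc = 8L, n_bins = 32L,
                         lambda = 2, gaussian_pulse_bin = 1L,
                         donut_pulse_bin = n_bins %/% 2L) {
  set.seed(seed)
  tm <- timing_config(period_ns = 25, n_bins = n_bins,
                      gaussian_pulse_bin = gaussian_pulse_bin,
                      donut_pulse_bin = donut_pulse_bin)
  cnt <- array(stats::rpois(nr * nc * n_bins, lambda), c(nr, nc, n_bins))
  tcspc_stack(cnt, tm, 40)
}

# Analytic Gaussian spot image (no noise).
gaussian_spot_image <- function(sigma_nm = 50, pixel_size_nm = 10,
                                n_px = 101L, center_nm = NULL) {
  if (is.null(center_nm)) center_nm <- rep(n_px / 2 * pixel_size_nm, 2L)
  xc <- (seq_len(n_px) - 0.5) * pixel_size_nm
  X <- matrix(xc, n_px, n_px, byrow = TRUE)
  Y <- matrix(xc, n_px, n_px)
  v <- exp(-((X - center_nm[1L])^2 + (Y - center_nm[2L])^2) / (2 * sigma_nm^2))
  intensity_image(v, pixel_size_nm)
}

# Direct per-pixel loop phasor transform: the independent oracle for the
# vectorised implementation.
phasor_loop_oracle <- function(decay, harmonic = 1L) {
  L <- decay$window_len
  dt <- decay$bin_width_ns
  omega <- 2 * pi * harmonic / (L * dt)
  t_k <- (seq_len(L) - 0.5) * dt
  d <- dim(decay$counts)
  g <- s <- matrix(NA_real_, d[1L], d[2L])
  for (r in seq_len(d[1L])) for (c in seq_len(d[2L])) {
    cc <- decay$counts[r, c, ]
    tot <- sum(cc)
    if (tot > 0) {
      g[r, c] <- sum(cc * cos(omega * t_k)) / tot
      s[r, c] <- sum(cc * sin(omega * t_k)) / tot
    }
  }
  list(g = g, s = s, omega = omega)
}

# Wrapped exponentially-modified-Gaussian CDF over one laser period:
# independent model of the simulated arrival-time distribution.
wrapped_emg_cdf <- function(x, t0, tau, sigma, period) {
  emg <- function(u) {
    z <- (u - t0) / sigma
    f <- stats::pnorm(z) -
      exp(sigma^2 / (2 * tau^2) - (u - t0) / tau +
            stats::pnorm(z - sigma / tau, log.p = TRUE))
    pmax(pmin(f, 1), 0)
  }
  # photons later than one period fold into the next cycle
  emg(x) - emg(0) + emg(x + period) - emg(period)
}
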