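---
title: "Phasor-FSTM: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasor-FSTM: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement being modelled

Phasor-FSTM is a multicolor super-resolution scheme for a laser-scanning
confocal microscope with time-correlated single photon counting (TCSPC).
Within each laser period `T`, the sample is excited twice: first by a
Gaussian-profile focus, then — after a delay long enough for the first
excitation to decay — by a donut-profile focus with zero central
intensity. Every detected photon is tagged with its arrival time and
binned into one of `n_bins` time channels, so a single scan yields a
`rows x cols x n_bins` photon histogram that interleaves, along the time
axis, a complete fluorescence decay excited by each beam.

Three processing steps recover multicolor super-resolution images:

1. **Temporal demultiplexing.** The time channel holding the donut pulse
   peak is the boundary `b`; bins `[0, b)` form the Gaussian-beam decay
   stack and `[b, n_bins)` the donut-beam stack (the boundary bin belongs
   to the donut window so the donut pulse peak carries donut photons).
   The partition is a half-open split of integer counts, hence exactly
   lossless per pixel.
2. **Phasor unmixing.** Each pixel's decay is mapped to first-harmonic
   Fourier coordinates
   `g = sum(c_k cos(w t_k)) / sum(c_k)`, `s = sum(c_k sin(w t_k)) / sum(c_k)`
   with `w = 2 pi / (window duration)` and `t_k` the bin centres. A
   mono-exponential decay of lifetime `tau` sits at
   `g = 1/(1 + (w tau)^2)`, `s = w tau/(1 + (w tau)^2)` — the universal
   semicircle — and mixtures lie on chords with photon-fraction weights.
   Pixels are assigned to dyes by circular gates in phasor space; a dye's
   Gaussian-window and donut-window photon totals on its assigned pixels
   form the component images `I_g` and `I_d`.
3. **Spatial modulation.** `I_s = max(I_g - delta * I_d, 0)` with
   `delta = 2`. Because the donut excites only the periphery of the
   confocal spot, the subtraction removes peripheral signal and narrows
   the effective PSF. Optional Richardson–Lucy deconvolution with the
   effective PSF sharpens further; pseudo-color tinting and additive
   composition produce the multicolor overlay.

Using one frequency per *split window* (not per full period) deserves a
note: with `w` matched to the window, the boundary terms of the Fourier
integral cancel (`exp(i w T') = 1`), so a window-truncated, renormalised
exponential still lands exactly on the semicircle; truncation bias would
otherwise be ~4% of the coordinate scale for the slowest dye.

## Calibration

Measured phasors are rotated and scaled relative to theory by the pulse
position within the window and by the detection chain's temporal blur
(IRF). Both effects are multiplicative in Fourier space and identical
for all dyes, so a single reference of known lifetime fixes them: the
complex correction `z_theory(tau_ref) / z_measured(ref)` is applied to
every pixel. The package simulates the reference (a lifetime-standard
measurement it cannot take on real hardware) with the same timing and
IRF via `simulate_reference_decay()`; it is synthetic and labelled as
such. Residual error after calibration comes from the photons a window
loses to its neighbour (≈4% of Gaussian-beam photons for a 3.8 ns dye at
a 12.1 ns sub-window) and is below 0.005 phasor units in the shipped
checks — comfortably inside the 0.02 semicircle tolerance.

## The acquisition simulator

The simulator is the package's testbed and defines its study conditions.
Per pixel, dye, and beam, the photon count is Poisson with mean given by
(emitter density ⊛ beam PSF) × brightness; each photon's arrival time is
`pulse peak + Exp(tau) + N(offset, sigma_IRF)`, wrapped modulo `T` and
binned (TCSPC behaviour: late photons fold into early bins). Each
(dye, beam) pair draws from its own seed substream, so adding a dye
never perturbs existing draws.

Fixed defaults, with reasons:

| Parameter | Default | Why |
|---|---|---|
| Laser period `T` | 25 ns (40 MHz) | a repetition rate is not specified by the instrument description; 25 ns with a half-period pulse delay lets a 3.8 ns dye decay to exp(-12.1/3.8) ≈ 4% before the donut pulse |
| Time channels | 256 (Δt ≈ 97.7 ps) | the stated TCSPC sampling |
| Pulse bins | 4 (Gaussian), 128 (donut) | see above |
| Excitation | λ = 635 nm, NA 1.40 | the stated optics |
| Gaussian FWHM | 0.40 λ = 254 nm | the *measured* confocal resolution, not the diffraction formula, so resolution comparisons start from the instrument's real baseline |
| Donut profile | I(r) ∝ r² exp(−r²/r_p²), r_p = 0.6 × FWHM_g | the actual 0/π-phase "3D cage" beam is not numerically specified; this is the standard single-parameter donut surrogate with zero centre |
| IRF | Gaussian, σ = 0.10 ns, offset 0 | typical PMT + TCSPC chain; no instrument value is given |
| Beam powers | equal by default | the detected-photon ratio per structure is not published; the four-color benchmark instead pins the *observed* split (59.31% / 40.69%) |

What the simulator deliberately does **not** model: vectorial/3-D PSFs,
detector afterpulsing, photobleaching kinetics, dark counts (available
as a config, default 0), and pixel cross-talk. Passing tests therefore
demonstrate correctness of the *processing chain* under ideal two-beam
TCSPC statistics, not robustness to every instrument artefact.

### Ground-truth labels

The simulator's dominant-dye label map is the scoring target for
unmixing accuracy. A literal rule "label = argmax of expected photons
wherever any are expected" is degenerate: PSF blur makes expected maps
positive in arbitrarily dim halos, and a pixel whose Gaussian window is
expected to hold fewer photons than the phasor definedness threshold
(`min_photons = 10`) can never be assigned, by design. Labels are
therefore floored at a *measurability* criterion: a pixel is a scoring
target only if its Gaussian-window expectation is at least twice
`min_photons` (20 photons), which keeps definedness failures below ~1%
among targets so that accuracy scores measure identification rather than
photon starvation at structure edges.

## Analysis parameters that matter

- **`min_photons` (default 10).** Below ~10 photons the per-pixel phasor
  is shot-noise dominated (sd ≥ 0.22); such pixels are excluded rather
  than misassigned.
- **Phasor smoothing (default 3×3 median, 1 pass).** Median filtering of
  `g` and `s` is the standard pre-gating noise reduction; it respects
  undefined pixels and never mixes photon totals. How much pooling is
  needed depends on the dye set: with N photons a phasor coordinate has
  sd ≈ 1/sqrt(2N), and distinguishing 3.3 ns from 3.8 ns at
  `w = 2π/12.5 ns⁻¹` means resolving a 0.06 separation. Per photon the
  two decays differ by ≈0.01 nat of information, so ≥500 pooled photons
  are needed regardless of method; at the reference operating point
  (~21 Gaussian photons/pixel image-wide) that is a few tens of pixels,
  i.e. 5×5 median × 3 passes. The four-color benchmark uses exactly
  that; these are analysis settings readable off the phasor-cloud
  tightness, not tuned against ground truth.
- **Gates (default radius 0.1, centres from lifetimes).** Centres start
  at the theoretical semicircle points but real clusters are displaced
  along mixing chords by concentration gradients, so `refine_gates()`
  recentres them on the observed clusters (photon-weighted Lloyd
  iterations; nearest-centre partitioning keeps overlapping gates split
  at their bisector instead of collapsing). The benchmark uses radius
  0.2 ≈ 3 pooled-noise standard deviations. Overlapping circles are
  legal; containment → nearest centre → lowest index is the fixed
  assignment order.
- **`delta` (default 2).** The published operating weight. `auto_delta()`
  is a documented heuristic (grid search minimising spot FWHM subject to
  clipped-energy ≤ 30% of the Gaussian image) and is *not* a derivation
  of the closed-form weight; on sparse bead images the energy budget can
  reject large weights, in which case it falls back to 2 with a warning.
- **Boundary detection.** The donut pulse bin is found as the leading
  edge of the second lobe of the smoothed global decay (first increment
  ≥ half the maximum increment below the lobe peak). With a slow dye the
  lobe top is flat and its argmax wanders ±3 bins between frames; the
  leading edge is frame-stable, matching the physical fact that the
  boundary is fixed by the optics.

## Numerical choices

- Time bin `k` (0-based) covers `[kΔt, (k+1)Δt)`; representative time is
  the bin centre. Half-open windows make photon conservation exact.
- Counts are stored as 16-bit unsigned TIFF pages (observed per-pixel
  maxima are ~119); intensity images as single-page 32-bit TIFF scaled
  to [0,1] with the scale in the JSON sidecar (round trip exact to
  ~2⁻³²).
- Subtraction clips negatives to zero (the published images are
  non-negative; the clipping rule itself is unstated).
- Richardson–Lucy uses circular FFT convolution; 0 iterations is the
  identity and total intensity is conserved to within 1%.
- The object perimeter uses the Crofton 4-direction estimator
  (bit-identical to scikit-image's `perimeter_crofton`), because the
  form factor `FF = P²/(4πA)` is estimator-sensitive and must be
  reproducible. Discretisation lets a digital disk's FF exceed 1
  slightly ([0.9, 1.15] is the accepted band).
- Skeletons come from Zhang–Suen thinning; junction pixels (≥3 skeleton
  neighbours, 8-connected) are merged into clusters before counting, and
  branches are the connected segments left after removing junction
  pixels, so a "Y" is 3 branches / 1 junction and an "X" is 4 / 1.
- Adaptive thresholding uses an exact integral-image local mean
  (replicate borders); an FFT box filter leaves ~1e-17 negatives in
  flat-zero regions, which would spuriously fire `value > mean + 0`.
- 3-D z-stacks are processed as independent 2-D planes with shared gate
  configuration.

## Known limitations and one negative result

- **Resolution at the default donut.** With the pinned conditions
  (Gaussian FWHM 0.40λ, `r_p = 0.6 FWHM_g`, equal beam photons,
  `delta = 2`) the effective subtraction PSF is
  `h(r) ∝ e^(-u)(1 - 2u)` with `u = r²/(2σ²)`, whose FWHM is 0.212λ
  analytically; the bead-field benchmark measures 0.20–0.21λ. Reaching
  the reported ~0.19λ requires either deconvolution (which the published
  profiles included) or a slightly tighter donut ring — at
  `delta·(donut/gaussian photon ratio) ≈ 2.7` effective weight the
  analytic width hits 0.19λ. The package reports the undeconvolved
  subtraction value.
- **Hard assignment.** All of a pixel's photons go to one dye; fractional
  decomposition of >2 components per pixel is explicitly out of scope.
- **Fit scope.** `fit_monoexp` is a count-weighted log-linear tail fit;
  near its information bound (~2% relative sd at 1e4 photons for a
  0.3 ns dye) single estimates occasionally exceed 5% error, which is a
  property of the photon budget, not the estimator.
- **Benchmark sizes.** The shipped checks use 256×256 scenes (four-color
  benchmark), a 12-bead 256×192 field (resolution), 40×40 uniform fields
  (semicircle), and 1e4–1e6-photon reference decays: sizes at which every
  quantity of interest is statistically stable while a full run stays in
  the tens of seconds on one core.
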