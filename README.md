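# phasorFSTM

Multicolor super-resolution processing for dual-beam fluorescence
lifetime imaging (FLIM), plus a full acquisition simulator so the chain
can be validated without instrument data.

## The problem and the method

On a confocal microscope with TCSPC detection, a single-wavelength
pulsed laser can excite the sample twice per period `T`: first with a
Gaussian focus, then — after the first excitation has decayed — with a
donut focus whose central intensity is zero. Every photon is tagged with
its arrival time, so one scan records, per pixel, two interleaved
fluorescence decays. Labelling up to four structures with spectrally
similar dyes of distinct lifetimes (0.3 / 1.0 / 3.3 / 3.8 ns) then lets
one detector separate them *temporally* instead of spectrally:

1. **Demultiplex** — the time channel of the donut pulse peak is the
   boundary `b`; bins `[0, b)` are Gaussian-beam photons, `[b, N)` donut
   photons (exact integer partition).
2. **Phasor unmixing** — each pixel's decay maps to
   `g = Σ c_k cos(ω t_k) / Σ c_k`, `s = Σ c_k sin(ω t_k) / Σ c_k`,
   `ω = 2π / (window duration)`. Mono-exponential dyes sit on the
   universal semicircle at `(1, ωτ) / (1 + (ωτ)²)`; circular gates in
   `(g, s)` space assign pixels (and their photons) to dyes, giving
   per-dye images `I_g` and `I_d` for the two beams.
3. **Weighted subtraction** — `I_s = max(I_g − δ·I_d, 0)` with `δ = 2`
   removes the periphery of the confocal spot that the donut beam
   excites, narrowing the effective PSF to roughly a fifth of the
   wavelength; pseudo-colored channels are superimposed for the final
   multicolor image.

The package implements every step (file I/O, boundary detection,
splitting, phasor transform, lifetime-standard calibration, median
smoothing, gate construction/refinement/assignment, component
extraction, subtraction, Richardson–Lucy deconvolution, composition) and
a quantification toolkit (profile FWHM, signal-to-background ratio,
unmixing precision/recall/F1 against ground truth, adaptive-threshold
object identification, form factors, skeleton branch/junction counts).
The simulator generates dual-beam TCSPC stacks from ground-truth scenes
with Poisson statistics, mono-exponential kinetics, and a Gaussian IRF.

## Worked example

The shipped demo config simulates a two-dye bead field (1.0 ns and
3.8 ns dyes, 23-nm beads) and runs the whole chain:

```r
library(phasorFSTM)
cfg <- pipeline_config(system.file("extdata", "demo-two-color.yaml",
                                   package = "phasorFSTM"))
bundle <- run_pipeline(cfg, output_dir = "demo-out")
m <- bundle$metrics
```

Printed metrics for this config (seed 1):

```
boundary 128 | gaussian 50.54% donut 49.46% of 239906 photons
     gaussian donut
mito    59543 56841
lyso    58466 58257
mito: FWHM 137.1 +/- 2.9 nm (n=6)
lyso: FWHM 130.4 +/- 1.8 nm (n=6)
```

Reading this: the detected boundary is time channel 128; the Gaussian /
donut photon percentages sum to 100% of the 239,906 recorded photons;
the table is the per-dye, per-beam photon bookkeeping after gating
(assigned + unassigned = per-beam totals, exactly); and the per-channel
mean FWHMs of the super-resolved bead images are ≈130–137 nm ≈ 0.21λ at
λ = 635 nm, versus ≈254 nm (0.40λ) for the confocal channel.

A four-dye organelle scene at the reference operating point (mean 35.26
photons/pixel on 256×256, 59.31% of photons in the Gaussian channel):

```r
fb <- fourcolor_benchmark(seed = 1)
fb$scores$per_class
#>   class precision recall    f1
#> 1     1     1.000  1.000 1.000   # nucleus (1.0 ns)
#> 2     2     1.000  0.998 0.999   # mitochondrion (0.3 ns)
#> 3     3     0.993  0.865 0.925   # microtubule (3.3 ns)
#> 4     4     0.612  0.972 0.751   # lysosome (3.8 ns)
fb$scores$macro_f1
#> [1] 0.919
```

The 3.3 / 3.8 ns pair is the hard case — their phasor centres are only
0.06 apart at this window frequency — and dominates the residual error.

A command-line front end wrapping the same functions is installed at
`system.file("cli", "phasor-fstm.R", package = "phasorFSTM")` with
subcommands `simulate`, `demux`, `phasor`, `unmix`, `fstm`, `metrics`,
and `all`.

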