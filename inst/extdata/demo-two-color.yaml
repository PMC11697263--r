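# Demo: two-color bead scene, simulated dual-beam acquisition.
seed: 1
input:
  simulation:
    extent_nm: [3840, 3840]
    optics:
      wavelength_nm: 635
      numerical_aperture: 1.40
      pixel_size_nm: 40
    timing:
      period_ns: 25
      n_bins: 256
      gaussian_pulse_bin: 4
      donut_pulse_bin: 128
    irf:
      sigma_ns: 0.1
      offset_ns: 0
    dyes:
      - {name: mito, lifetime_ns: 1.0, brightness: 1}
      - {name: lyso, lifetime_ns: 3.8, brightness: 1}
    structures:
      - {type: bead, dye: mito, center_nm: [1000, 1000], diameter_nm: 23, amplitude: 20000}
      - {type: bead, dye: mito, center_nm: [2800, 1200], diameter_nm: 23, amplitude: 20000}
      - {type: bead, dye: mito, center_nm: [1200, 2800], diameter_nm: 23, amplitude: 20000}
      - {type: bead, dye: lyso, center_nm: [2700, 2700], diameter_nm: 23, amplitude: 20000}
      - {type: bead, dye: lyso, center_nm: [1900, 1900], diameter_nm: 23, amplitude: 20000}
      - {type: bead, dye: lyso, center_nm: [2900, 600], diameter_nm: 23, amplitude: 20000}
demux:
  min_prominence: 0.05
phasor:
  harmonic: 1
  min_photons: 10
  smooth: {kernel_px: 3, passes: 1}
  calibration: {tau_ref_ns: 3.8, n_photons: 1000000}
  gates: {radius: 0.15}
fstm:
  delta: 2
  deconvolve_iterations: 0
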