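# Default configuration of the hpmri virtual experiment.
# Values mirror hpmri::default_config(); any subset may be overridden,
# unknown keys are rejected.
field:
  B0: 4.7          # tesla
  f0: 50.7         # MHz (Hz per ppm)
  gamma: 1070.8    # Hz/G, carbon-13
  b1_max: 2.0      # gauss
metabolites:
  t2_default: 0.1        # s
  urea_shift_ppm: 163.5
design:
  flip_pyruvate: 20      # degrees
  flip_lactate: 90
  pass_halfwidth_ppm: 0.5
  tbw_spectral: 3.5
  max_ripple: 0.01
  ripple_margin: 0.9
  tbw_spatial: 4
  slice_thickness: 20    # mm
  grad_max: 10           # G/cm
  slew_max: 200          # G/cm/ms
  dwell: 4               # us
  subpulse_flat_ms: 0.40
  b1_peak_max: 0.4       # gauss
  n_taps_max: 24
epi:
  matrix: [16, 16]
  fov: [80, 80]          # mm
  slice_thickness: 20
  adc_dwell_us: 16
csi:
  matrix: [8, 8]
  fov: [80, 80]
  slice_thickness: 20
  flip: 10               # degrees, hard pulse
  sw: 25000              # Hz
  np: 2048
  tr_ms: 82
slab:
  flip: 5
  sw: 10000
  np: 2048
  tr_ms: 1200
  thickness_mm: 40
schedule:
  interval: 3            # s between metabolite pairs
  duration: 60           # s -> 20 frames per metabolite
  start_delay: 20        # s after injection start
  flip_pyruvate: 20
  flip_lactate: 90
phantom:
  matrix: [64, 64]
  fov: [80, 80]
  slice_thickness: 20
  b0_rms: 15             # Hz
  b0_max: 60
  chest_offset_hz: 60
  kpl_tissue: 0.02       # 1/s
  kpl_kidney: 0.05
  kpl_chest: 0.03
  t1_lactate: 33         # s
  inflow_peak_t: 12      # s
  inflow_shape: 2.5
  urea_amp: 0.5
  t2star_ms: 30
noise:
  epi_sigma: 0
  csi_sigma: 0
  slab_sigma: 0
calibration:
  search_halfwidth_hz: 300
  min_snr: 5
recon:
  lb_hz: 12              # exponential apodization
  window_halfwidth_ppm: 1.5
seed: 1
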