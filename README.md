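# hpmri — metabolite-specific hyperpolarized ¹³C MRI, simulated end to end

Hyperpolarized [1-¹³C]pyruvate boosts ¹³C MR signal by orders of magnitude,
but the polarization is non-renewable: it decays with T1 (~65 s at 4.7 T)
and every RF pulse consumes part of it. Imaging the injected pyruvate and
its metabolic product [1-¹³C]lactate therefore rewards sequences that
excite one metabolite at a time — a spectral-spatial RF (SSRF) pulse per
metabolite feeding a single-shot flyback EPI readout — over conventional
chemical shift imaging (CSI), which spends one excitation per phase-encode
step on every species at once.

`hpmri` is an R package that rebuilds that entire experiment as a
desk-scale simulation, for MR physicists and sequence developers who want
to study the design trade-offs quantitatively without a scanner:

* **SSRF pulse design** — complex least-squares spectral FIR on a flyback
  sub-pulse train with sub-pulse envelope correction, large-tip
  (Cayley–Klein) refinement, and Bloch-verified acceptance: uniform
  excitation over a ±0.5 ppm passband with ≤1 % ripple while rejecting the
  other species of the pyruvate spin system (lactate 184.3, alanine 177.7,
  pyruvate-hydrate 180.4, vs pyruvate 172.0 ppm) to ≤1 %.
* **Bloch simulation** — hard-pulse rotations, exact per sample, over
  (position × frequency) grids, plus an emulation of the swept-frequency
  1D profile *measurement* used to verify pulses on a scanner.
* **Synthetic rat-abdomen phantom** — seeded compartment masks (liver,
  kidneys, chest, vasculature, urea reference vial), band-limited B0 map,
  and a hyperpolarized magnetization budget with unidirectional
  pyruvate→lactate exchange ($\dot M_P = i(t) - M_P/T_{1P} - k_{PL}M_P$,
  $\dot M_L = k_{PL}M_P - M_L/T_{1L}$) driven by a gamma-variate inflow.
* **Virtual scanner** — dynamic alternating 20°/90° metabolite-specific
  flyback EPI (16×16, 80 mm FOV, every 3 s for 60 s), dynamic CSI
  (8×8, 10° hard pulse, 25 kHz/2048 pts, TR 82 ms), and the 5° slab
  pre-scan spectrum.
* **Reconstruction** — FFT recon with subvoxel chemical-shift displacement
  correction (fractions of the read/phase bandwidths), CSI peak-height
  metabolite maps after 12 Hz exponential apodization, SNR-normalized
  image series, ROI time curves, and a kPL fitter.
* **Automated center-frequency calibration** — find the pyruvate peak in
  the slab spectrum (parabolic sub-bin refinement), retune the carrier,
  set both pulse offsets relative to pyruvate, then trigger the EPI run.

## Worked example

```r
library(hpmri)
fp  <- field_params()                      # 4.7 T, 50.7 MHz, B1max 2 G
pyr <- design_metabolite_pulse("pyruvate") # 20 deg substrate pulse
lac <- design_metabolite_pulse("lactate")  # 90 deg product pulse
pyr
#> <ssrf_pulse> 20.0 deg, 7.86 ms, 11 sub-pulses, B1peak 0.195 G, center offset +0.0 Hz
lac
#> <ssrf_pulse> 90.0 deg, 11.36 ms, 16 sub-pulses, B1peak 0.374 G, center offset +0.0 Hz

## verify the pyruvate pulse against its own spec with the Bloch simulator
prof <- simulate_profile(pyr, 0, seq(-650, 650, length.out = 521), fp)
m <- measure_band_metrics(prof, 0,
       passband  = c(-25.35, 25.35),              # +/-0.5 ppm at 50.7 Hz/ppm
       stopbands = list(alanine = c(263.64, 314.34),
                        hydrate = c(400.53, 451.23),
                        lactate = c(598.26, 648.96)),
       nominal_flip = 20)
sprintf("passband ripple %.4f, stopband max %.4f, half-width %.3f ppm",
        m$passband_ripple, max(m$stopband_ripple), m$pass_halfwidth_hz / 50.7)
#> "passband ripple 0.0054, stopband max 0.0044, half-width 0.608 ppm"
```

The 20° pulse excites pyruvate to within 0.5 % of nominal across a
passband wider than the specified ±0.5 ppm while exciting the neighbouring
resonances by less than 0.5 % of full signal; the pulse lands in the same
duration/peak-B1 class as the published reference designs (6.3 ms/0.2 G
and 13.3 ms/0.3 G). The full pipeline — design, profile QC, phantom,
automated calibration, dynamic EPI + CSI, reconstruction, ROI curves and
an HTML report — runs from one call:

```r
res <- run_full_experiment(default_config(), "out")   # a few minutes
res$cal
#> <calibration_result> pyruvate at ... Hz (SNR ...)
```

A thin command-line front end wraps the same functions:

```sh
inst/cli/hpmri design --metabolite lactate --out waveforms/
inst/cli/hpmri run --seed 1 --out out/
```

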