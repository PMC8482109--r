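---
title: "Metabolite-specific hyperpolarized 13C EPI: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolite-specific hyperpolarized 13C EPI: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

hpmri is a desk-scale virtual experiment for metabolite-specific imaging of
hyperpolarized [1-13C]pyruvate and its product [1-13C]lactate at 4.7 T
(carrier 50.7 MHz). It covers the whole chain a scanner study would cover:
spectral-spatial RF (SSRF) pulse design, Bloch-simulated and
"measured" excitation-profile verification, dynamic flyback-EPI and CSI
acquisition from a synthetic rat-abdomen phantom carrying a hyperpolarized
magnetization budget, reconstruction with chemical-shift displacement
correction, and an automated real-time center-frequency calibration.
This vignette explains the models, their assumptions, and the design
decisions that were genuinely open.

## Conventions

All frequencies are Hz offsets from the *nominal pyruvate resonance at zero
B0*. Metabolites sit at `ppm_to_hz(shift - 172.0)`; a voxel adds its B0
offset; the scanner demodulates at a carrier (0 when tuned to nominal
pyruvate); pulse center offsets are relative to the carrier. One ppm is
exactly 50.7 Hz because the carrier is specified in MHz. In the rotating
frame, positive off-resonance rotates transverse magnetization
counterclockwise about +z; all phase-sensitive tests assume this.

Images use voxel-center coordinates with 0-based index `i` at position
`(i - n/2) * dx`, DC at index `n %/% 2`; the read axis is the first array
dimension.

## SSRF pulse design

An SSRF pulse is a train of identical slice-selective sub-pulses whose
amplitudes follow a spectral FIR filter. The sub-pulse is a Hamming-windowed
sinc (spatial time-bandwidth product 4) on the flat-top of a trapezoidal
slice-select lobe; a minimum-time flyback rewinder refunds the lobe area
after every sub-pulse, and a final half-area lobe refocuses the slice. The
sub-pulse period sets the spectral replication period of the design; with
the default 0.40 ms flat-top, 4 µs dwell, 10 G/cm gradient ceiling and
200 G/cm/ms slew, the period is about 0.7 ms, i.e. a 1.43 kHz replication
bandwidth — wide enough that all stopbands of both metabolite designs fit
unfolded. The 200 G/cm/ms slew default is ordinary for small-bore gradient
inserts and is what makes a 6–8 ms pyruvate pulse possible at all: at
50 G/cm/ms the rewinder alone stretches the sub-pulse period past 1 ms and
no ripple-feasible design fits the published duration class.

The spectral filter is a complex least-squares FIR with Lawson-style
iterative band reweighting, with three refinements that practice forced:

* **Sub-pulse envelope.** Off-resonant spins precess *during* each 0.4 ms
  sub-pulse, so the effective spectral response is the tap response times
  the sub-pulse's own Fourier envelope. The envelope is folded into the
  design matrix (exact in the small-tip limit); stopbands are evaluated at
  their true frequencies because the envelope, unlike the tap response, is
  not periodic.
* **Passband-center anchor.** Flip calibration pins the response at the
  passband center, so ripple must be centered there too: a strongly
  weighted design row forces the response to 1 at f = 0, otherwise the
  calibrated response can leave the band by twice the least-squares ripple.
* **Transition control.** The bands cover only a small part of the
  replication period; unconstrained least squares can meet every band spec
  with wild out-of-band response and multi-gauss tap excursions. A weak
  (1%-weight) pull toward zero across the transition regions, minus a
  one-resolution-cell guard around each band edge, keeps the taps tame.

The 1% excitation-ripple budget is specified as a fraction of full
excitation (`|Mxy|/sin(flip)`), and the sine nonlinearity means the filter
ripple must be tighter than 1% at large tips: the stopband target is
`asin(r sin(theta))/theta` and the passband target is solved from
`sin(theta (1+e))`. Even so, at 90° the small-tip linear model
underestimates stopband excitation: second-order large-tip leakage floors
near 1–1.5% regardless of the filter ripple. The designer therefore
verifies every candidate with the full Bloch simulator, and when the
least-squares taps fail that gate it re-optimizes them against a reduced
large-tip model — a Cayley–Klein hard-pulse propagation of the tap train,
exact for the spectral dimension at slice center — before re-checking. The
tap count is the smallest that passes the Bloch gate; each candidate must
also stay below a 0.4 G design peak-B1 bound (20% of the coil's 2 G
ceiling, amplifier linear-regime headroom): without that bound the
smallest-count tie-break accepts short but B1-hungry designs far outside
the 0.2–0.3 G class of the reference pulses.

With the defaults this yields a 7.9 ms, 11-sub-pulse, 0.195 G pyruvate
pulse (20°) and an 11.4 ms, 16-sub-pulse, 0.374 G lactate pulse (90°),
against published reference designs of 6.3 ms/0.2 G and 13.3 ms/0.3 G whose
gradient hardware was not reported; durations are therefore judged as
tolerance bands, while ripple, flips and passband width are hard
specifications.

```{r}
library(hpmri)
pyr <- design_metabolite_pulse("pyruvate")
lac <- design_metabolite_pulse("lactate")
```

## Bloch simulation and profile measurement

`simulate_profile()` composes one exact rotation per waveform sample about
the effective field (B1; gradient times position plus off-resonance along
z) at every point of a (position x frequency) grid. Because the waveforms
are piecewise constant, each per-sample rotation is the exact solution of
the Bloch equation for that interval; no relaxation is applied during the
pulse (pulse durations are milliseconds against T1/T2 of tens of seconds
to minutes). Default verification grids are z in [-3, 3] cm (121 points)
and f in [-600, 600] Hz (241 points), matching the swept verification
range; grid density was chosen for convergence of the band metrics, and
band-edge quantities are refined by linear interpolation between grid
points (the passband half-width at the ripple criterion in particular, so
it is not quantized to the grid spacing).

The swept "measurement" (`measure_pulse_profile()`) reproduces the 1D
profile experiment: the pulse center frequency is stepped over ±600 Hz on
an on-resonance water cylinder (proton mode in the original experiment; a
single on-resonance species here), and after each excitation the spatial
projection is read out through a finite 64-sample k-space acquisition with
magnitude reconstruction — a genuinely different code path from the direct
grid simulation, including the resolution loss of a real projection
readout. A spin at offset -d sees the same excitation as an on-resonance
spin under a pulse shifted by +d, so sweep step d fills the profile column
at f = -d. Agreement between the two paths within 5% RMS of peak is part of
the acceptance surface.

## Phantom and hyperpolarized dynamics

`build_rat_phantom()` draws ellipse-based compartments (chest/heart, liver,
left/right kidney, a vascular strip, and an external urea reference vial
disjoint from all tissue) at plausible coronal positions, with a small
seeded jitter, plus a band-limited random B0 map scaled to a 15 Hz RMS
inside the body (clamped at ±60 Hz, zero outside). All randomness flows
from one integer seed; the same seed reproduces the phantom bit-exactly.

Magnetization follows a unidirectional two-site exchange with T1 loss and a
gamma-variate arterial inflow:

$$\dot M_P = i(t) - M_P/T_{1P} - k_{PL} M_P, \qquad
  \dot M_L = k_{PL} M_P - M_L/T_{1L}$$

advanced by an exact per-voxel exponential integrator (inflow sampled at
substep midpoints, 0.25 s substeps while inflow is active; without inflow a
single step of any length is exact). RF consumption is the standard
`sin`/`cos` split per excitation, weighted by the pulse's Bloch profile at
each voxel's offset. Defaults: pyruvate T1 = 65 s (the aqueous-solution
value at this field), lactate T1 = 33 s (literature-typical, not reported
in the reference experiment), kPL = 0.02 s^-1 in tissue, 0.05 s^-1 in
kidney, inflow peaking 12 s after injection start (matching a ~12 s
injection). T2 defaults to 0.1 s and T2* to 30 ms (about 10 Hz linewidths).
None of these kinetic settings are fits to animal data; they are synthetic
study conditions, and nothing in the package claims to reproduce in vivo
signal curves. What the passing tests do show is that the *acquisition
physics and bookkeeping* — RF budgets, displacement, calibration — behave
quantitatively as the closed forms demand; what they cannot show is
fidelity to real rat metabolism, perfusion, motion, or coil behavior.

The chest compartment carries a fixed +60 Hz offset, placing it outside a
metabolite-selective passband but inside a CSI peak window — a synthetic
illustration of chest signal appearing in spectroscopic but not selective
imaging, not a validated mechanism. The urea vial is thermal (Gd-doped in
the original setup): its signal never depletes and is visible to the CSI
and slab acquisitions only.

## Virtual scanner and reconstruction

The flyback EPI trajectory is a timing model: N lines acquired on
same-polarity flat-tops, separated by minimum-time rewinders carrying the
phase blip, `delta_k = 1/FOV` exactly, so `bw_phase = 1/esp` by
construction and no odd/even correction is ever needed. Acquisition is the
discrete Fourier sum over phantom voxels with per-sample off-resonance
phase accrual and T2 decay, plus complex white Gaussian noise. CSI
(8 x 8, 10° hard pulse, 25 kHz / 2048 points, TR 82 ms) spends one
excitation per phase encode and consumes every hyperpolarized species each
time — the RF budget that makes metabolite-specific EPI attractive: after
six CSI frames only `cos(10°)^384 = 0.0028` of the polarization survives
RF, versus `cos(20°)^20 = 0.288` after twenty pyruvate EPI frames.

EPI reconstruction is a plain centered inverse FFT; the chemical-shift
displacement of each metabolite (`df/bw_read` of FOV along read,
`df/bw_phase` along phase) is undone by multiplying k-space with the
conjugate of the modeled phase accrual — a subvoxel Fourier translation
that cancels the acquisition model exactly when `df` equals the
metabolite-minus-pulse-center offset. Whether the original reconstruction
used integer or subvoxel shifts was not stated; subvoxel is implemented
and tested as such. CSI reconstruction applies a 12 Hz exponential
apodization (line-broadening convention: adds 12 Hz to a Lorentzian FWHM),
a spatial inverse DFT across encodes and a spectral FFT, and takes each
metabolite's peak height within ±1.5 ppm of its resonance (windows stay
disjoint because the closest species are 3.9 ppm apart). Maps are reported
in SNR units against a median-based Rayleigh-consistent noise scale from
the outer 10% of the spectral axis; a `normalize = "none"` mode exists for
noiseless quantitative checks, where the "noise floor" would otherwise be
the far tails of the lines themselves and the maps would lose their
linearity in source amplitude.

## Automated center-frequency calibration

The pre-scan acquires a 5°, 10 kHz / 2048-point spectrum from a slab
covering liver, kidneys and the urea vial but excluding the chest, about
2 s before imaging starts. The tallest local maximum within ±300 Hz of
nominal pyruvate (generous against plausible B0 offsets, and excluding
urea at -431 Hz) is refined by three-point parabolic interpolation —
deterministic sub-bin accuracy on Lorentzian peaks, which is what makes
the downstream 0.1-voxel position requirement attainable: one 4.88 Hz bin
of residual error maps to about 0.08 voxels along the phase-encode axis.
Lactate is never detected directly (its peak is too weak this early); its
pulse offset is derived from the fixed 12.3 ppm pyruvate-lactate
separation. If no peak clears the SNR threshold the calibration raises an
error and no imaging frames are acquired. The original script's peak
picker and window were not published; tallest-peak-in-window with
parabolic refinement is this package's choice.

## Numerical choices and degenerate inputs

* Waveform dwell 4 µs; ADC dwell 16 µs (62.5 kHz readout bandwidth at
  16 x 16 / 80 mm).
* Flip calibration: multiplicative rescale with a root-finding fallback,
  0.05° internal tolerance, hard failure past 0.5°.
* Filter design: 128 design / 512 verification points per band, up to 400
  reweighting iterations, deterministic for identical inputs.
* Gradient lobes are discretized with midpoint-sampled ramps: junction
  slew never exceeds one increment and discrete areas equal the continuous
  trapezoid areas exactly; amplitudes are rescaled after rounding so the
  rewinder refunds the lobe area to machine precision.
* Degenerate inputs fail loudly: zero matrix dimensions, stopbands
  overlapping the passband (before or after folding), bands outside a
  simulated grid, extrapolating regrids, empty slabs, empty ROI masks,
  overlapping CSI windows, negative line broadening, unknown metabolites,
  unknown config keys (with the offending key path).
* Exchange integrator: `b - a` degeneracy handled by the analytic limit;
  `a = 0` implies no exchange, so the missing inflow cross-term multiplies
  zero.

## Problem sizes

The shipped test-suite and verification runs use desk-scale sizes chosen
as the package's working defaults: 32–64 voxel phantom grids, 241–1201
frequency points for profile checks, 53–66 sweep steps, 256–2048 spectral
points, and short (2–3 frame) dynamic series where the full 20-frame
schedule is not itself the property under test. The full protocol
(20 + 20 EPI frames, six 2048-point CSI frames, 64 x 64 phantom) runs in a
few minutes through `run_full_experiment()`.

## Known limitations

* 2D physics: through-plane selection reduces to mask weights; no 3D
  phantom, no slice-profile/through-plane interplay.
* No gradient-delay or eddy-current artifacts, no Nyquist ghosts (moot for
  flyback), no motion, no B1 inhomogeneity, no noise correlation.
* The kinetic model is unidirectional with voxel-independent dynamics; no
  perfusion or compartmental exchange after inflow, no alanine/bicarbonate
  dynamics (alanine exists only as a stopband target).
* The urea vial is a fixed-amplitude thermal reference, not a relaxing
  spin system.
* Pulse durations depend on unreported gradient hardware; they are matched
  to the reference designs as a class, not reproduced exactly.
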