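#' Locate the pyruvate resonance in a slab pre-scan spectrum
#'
#' Computes the magnitude spectrum of the slab FID, finds the tallest local
#' maximum within the search window (pyruvate dominates early post-injection
#' spectra, so tallest-peak is the tie-break), refines the frequency by
#' three-point parabolic interpolation, and reports the peak SNR against a
#' median-based noise floor from the outer 10% of the spectral axis.
#'
#' @param spectrum A single-FID `spectral_grid` from
#'   [acquire_slab_spectrum()].
#' @param search_window `c(lo, hi)` window (Hz, relative to the current
#'   carrier) to search; default +/- 300 Hz around nominal pyruvate.
#' @param min_snr Minimum acceptable peak SNR; below it a
#'   calibration-failure error is raised and no imaging should proceed.
#' @return List with `freq` (Hz, relative to the carrier) and `snr`.
#' @export
find_pyruvate_peak <- function(spectrum, search_window = c(-300, 300),
                               min_snr = 5) {
  np <- spectrum$np
  stopifnot(np >= 3)
  fid <- spectrum$fids[, 1, 1]
  fax <- spectral_axis(np, spectrum$sw)
  if (search_window[1] < fax[1] || search_window[2] > fax[np])
    stop("search window outside the spectral axis", call. = FALSE)
  mag <- Mod(fid_spectrum(fid))
  n_out <- ceiling(np * 0.05)
  sigma <- rayleigh_sigma(c(mag[seq_len(n_out)], mag[np - seq_len(n_out) + 1L]))
  if (sigma <= 0) sigma <- max(mag) * 1e-12 + .Machine$double.xmin
  sel <- which(fax >= search_window[1] & fax <= search_window[2])
  sel <- sel[sel > 1 & sel < np]
  is_max <- mag[sel] >= mag[sel - 1] & mag[sel] >= mag[sel + 1] &
    mag[sel] / sigma >= min_snr
  if (!any(is_max))
    stop("calibration failure: no peak above SNR ", min_snr,
         " in the search window", call. = FALSE)
  cand <- sel[is_max]
  i <- cand[which.max(mag[cand])]
  y0 <- mag[i - 1]; y1 <- mag[i]; y2 <- mag[i + 1]
  denom <- y0 - 2 * y1 + y2
  delta <- if (denom != 0) 0.5 * (y0 - y2) / denom else 0
  bin <- spectrum$sw / np
  list(freq = fax[i] + delta * bin, snr = y1 / sigma)
}

#' Compute pulse frequency offsets and reconstruction shifts
#'
#' Implements the retuning rule of the automated procedure: the scanner
#' carrier moves to the detected pyruvate frequency; the pyruvate pulse is
#' centered on the new carrier (offset 0) and the lactate pulse at the fixed
#' pyruvate-to-lactate shift (lactate is never detected directly — its peak
#' is too weak early after injection). Reconstruction shifts are the
#' spectral distance between each metabolite and its pulse's passband
#' center: zero when the passband is centered on the metabolite.
#'
#' @param pyruvate_freq Detected pyruvate frequency (Hz, relative to the
#'   pre-calibration carrier).
#' @param metab Metabolite table (must contain pyruvate).
#' @param pulses Named list of pulses (used for the offset names).
#' @param peak_snr Detected-peak SNR, carried through for bookkeeping.
#' @param field Field parameters.
#' @return An object of class `calibration_result`: `pyruvate_freq`,
#'   `carrier_hz` (new absolute carrier), `pulse_offsets`, `recon_shifts`,
#'   `peak_snr`.
#' @export
compute_offsets <- function(pyruvate_freq, metab = metabolite_table(),
                            pulses = NULL, peak_snr = NA_real_,
                            field = field_params()) {
  stopifnot("pyruvate" %in% metab$name)
  mets <- if (!is.null(pulses)) names(pulses) else c("pyruvate", "lactate")
  pulse_offsets <- vapply(mets, function(nm)
    metab_offset_hz(metab, nm, field), numeric(1))
  recon_shifts <- vapply(mets, function(nm)
    metab_offset_hz(metab, nm, field) - pulse_offsets[[nm]], numeric(1))
  structure(list(pyruvate_freq = pyruvate_freq,
                 carrier_hz = pyruvate_freq,
                 pulse_offsets = pulse_offsets,
                 recon_shifts = recon_shifts,
                 peak_snr = peak_snr),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> pyruvate at %+.2f Hz (SNR %.1f)\n",
              x$pyruvate_freq, x$peak_snr))
  for (nm in names(x$pulse_offsets))
    cat(sprintf("  %-10s pulse offset %+8.2f Hz, recon shift %+6.2f Hz\n",
                nm, x$pulse_offsets[[nm]], x$recon_shifts[[nm]]))
  invisible(x)
}

#' Automated center-frequency calibration followed by dynamic EPI
#'
#' The full real-time procedure: acquire the low-flip slab spectrum
#' (consuming `cos(flip)` of the in-slab magnetization), detect the
#' pyruvate resonance, retune the carrier to it, set both pulse offsets
#' relative to pyruvate, and trigger the dynamic EPI acquisition. On
#' calibration failure no EPI frames are acquired and the error propagates.
#'
#' @param phantom,state A `digital_phantom` and its `hp_state`.
#' @param schedule A [protocol_schedule()].
#' @param pulses Named list of calibrated pulses (pyruvate, lactate).
#' @param traj A `flyback_traj`.
#' @param seed Seed for all stochastic stages.
#' @param field,metab Constants.
#' @param slab,slab_flip,slab_sw,slab_np Slab pre-scan parameters (see
#'   [acquire_slab_spectrum()]).
#' @param search_halfwidth_hz Half-width of the peak search window (Hz).
#' @param min_snr Minimum peak SNR for the calibration to proceed.
#' @param noise_sigma EPI acquisition noise.
#' @param slab_noise_sigma Slab spectrum noise.
#' @param prescan_lead Seconds before the schedule's start delay at which
#'   the slab pre-scan is acquired (the scan happens after injection, just
#'   ahead of imaging).
#' @return List: `cal` (`calibration_result`), `frames` (EPI series),
#'   `state`, and `spectrum` (the slab `spectral_grid`).
#' @export
run_autocal_then_epi <- function(phantom, state, schedule, pulses, traj,
                                 seed = 1L,
                                 field = field_params(),
                                 metab = metabolite_table(),
                                 slab = list(axis = 2, range_mm = c(-40, 15)),
                                 slab_flip = 5, slab_sw = 10000,
                                 slab_np = 2048,
                                 search_halfwidth_hz = 300, min_snr = 5,
                                 noise_sigma = 0, slab_noise_sigma = 0,
                                 prescan_lead = 2) {
  t_slab <- max(0, schedule$start_delay - prescan_lead)
  if (state$t < t_slab)
    state <- evolve_hp_state(state, t_slab - state$t)
  pre <- acquire_slab_spectrum(phantom, state, slab = slab, flip = slab_flip,
                               sw = slab_sw, np = slab_np, field = field,
                               metab = metab, noise_sigma = slab_noise_sigma,
                               seed = seed, carrier_hz = 0)
  state <- pre$state
  peak <- find_pyruvate_peak(pre$spectrum,
                             c(-search_halfwidth_hz, search_halfwidth_hz),
                             min_snr)
  cal <- compute_offsets(peak$freq, metab, pulses, peak$snr, field)
  for (nm in names(pulses))
    pulses[[nm]] <- shift_pulse_center(pulses[[nm]], cal$pulse_offsets[[nm]])
  epi <- run_dynamic_epi(phantom, state, schedule, pulses, traj, field,
                         metab, noise_sigma, seed, carrier_hz = cal$carrier_hz)
  list(cal = cal, frames = epi$frames, state = epi$state,
       spectrum = pre$spectrum)
}
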