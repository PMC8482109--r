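## Frequency bookkeeping convention used across the virtual scanner:
## all frequencies are Hz offsets from the NOMINAL pyruvate resonance at
## zero B0. A metabolite resonates at metab_offset_hz() + b0_map; the
## scanner demodulates at carrier_hz (0 = tuned to nominal pyruvate);
## pulse center offsets are relative to the carrier.
metab_offset_hz <- function(metab, name, field = field_params()) {
  ppm_to_hz(met_row(metab, name)$shift_ppm -
              met_row(metab, "pyruvate")$shift_ppm, field)
}

#' Acquisition schedule for the dynamic metabolite-specific protocol
#'
#' @param interval Time between metabolite image pairs (s).
#' @param duration Total imaging duration (s); `floor(duration / interval)`
#'   frames are acquired per metabolite.
#' @param flips Named flips (degrees) per metabolite, pyruvate first.
#' @param start_delay Delay between injection start and first frame (s).
#' @return An object of class `protocol_schedule`.
#' @export
#' @examples
#' protocol_schedule(3, 60)  # 20 frames per metabolite
protocol_schedule <- function(interval = 3, duration = 60,
                              flips = c(pyruvate = 20, lactate = 90),
                              start_delay = 20) {
  stopifnot(interval > 0, duration >= 0, start_delay >= 0,
            !is.null(names(flips)))
  structure(list(interval = interval, duration = duration, flips = flips,
                 start_delay = start_delay,
                 n_frames = floor(duration / interval)),
            class = "protocol_schedule")
}

#' @export
print.protocol_schedule <- function(x, ...) {
  cat(sprintf("<protocol_schedule> every %g s for %g s (%d frames/metabolite), start %g s\n",
              x$interval, x$duration, x$n_frames, x$start_delay))
  invisible(x)
}

#' Construct a flyback EPI readout trajectory
#'
#' Timing model of an N-line flyback echo-planar readout: samples are
#' acquired only on the flat-tops of same-polarity readout lobes; flyback
#' rewinders (with the phase blip) separate consecutive lines, so the
#' acquired samples form a complete Cartesian grid with `delta_k = 1/FOV`
#' exactly and no odd/even line reversal.
#'
#' @param geom A [geometry2d()].
#' @param grad_max Readout gradient limit (G/cm).
#' @param slew_max Slew-rate limit (G/cm/ms).
#' @param adc_dwell_us ADC sample interval (microseconds); the readout
#'   bandwidth is `1/adc_dwell_us`.
#' @param field A [field_params()] object.
#' @return An object of class `flyback_traj`: per-sample `kx`, `ky` (1/cm)
#'   and `t_ms` matrices (readout index x line index), echo spacing
#'   `esp_ms`, `bw_read` and `bw_phase = 1/esp` (Hz), `readout_duration_ms`,
#'   readout gradient amplitude.
#' @export
#' @examples
#' tr <- make_flyback_trajectory(geometry2d(c(16, 16), c(80, 80), 20))
#' tr$bw_phase * tr$esp_ms / 1000  # == 1 by definition
make_flyback_trajectory <- function(geom, grad_max = 10, slew_max = 200,
                                    adc_dwell_us = 16,
                                    field = field_params()) {
  stopifnot(grad_max > 0, slew_max > 0, adc_dwell_us > 0)
  nr <- geom$matrix[1]; nl <- geom$matrix[2]
  fov_cm <- geom$fov / 10
  dk <- 1 / fov_cm                       # 1/cm, exact
  dwell_s <- adc_dwell_us * 1e-6
  g_read <- dk[1] / (field$gamma * dwell_s)
  if (g_read > grad_max)
    stop("infeasible trajectory: readout gradient ", signif(g_read, 3),
         " G/cm exceeds grad_max; increase the ADC dwell", call. = FALSE)
  dwell_ms <- adc_dwell_us / 1000
  ramp_ms <- g_read / slew_max
  flat_ms <- nr * dwell_ms
  area <- g_read * (flat_ms + ramp_ms)   # full positive lobe (G*ms/cm)
  rw <- min_time_lobe(-area, grad_max, slew_max, 4)
  rw_ms <- length(rw) * 4 / 1000
  esp_ms <- ramp_ms + flat_ms + ramp_ms + rw_ms
  kx <- (seq_len(nr) - 1 - nr %/% 2) * dk[1]
  ky <- (seq_len(nl) - 1 - nl %/% 2) * dk[2]
  t_ms <- outer(ramp_ms + (seq_len(nr) - 0.5) * dwell_ms,
                (seq_len(nl) - 1) * esp_ms, `+`)
  structure(list(geom = geom, kx = kx, ky = ky, t_ms = t_ms,
                 esp_ms = esp_ms, bw_read = 1 / dwell_s,
                 bw_phase = 1000 / esp_ms,
                 readout_duration_ms = nl * esp_ms,
                 g_read = g_read, adc_dwell_us = adc_dwell_us),
            class = "flyback_traj")
}

#' @export
print.flyback_traj <- function(x, ...) {
  cat(sprintf(paste0("<flyback_traj> %d x %d, esp %.3f ms, bw_read %.0f Hz, ",
                     "bw_phase %.0f Hz, readout %.1f ms\n"),
              x$geom$matrix[1], x$geom$matrix[2], x$esp_ms, x$bw_read,
              x$bw_phase, x$readout_duration_ms))
  invisible(x)
}

## Per-voxel demodulated frequency offsets (Hz) for one metabolite.
voxel_offsets <- function(phantom, metab, name, field, carrier_hz) {
  b0 <- phantom$b0_map
  off <- phantom$chest_offset_hz %||% 0
  if (off != 0) b0[phantom$masks$chest] <- b0[phantom$masks$chest] + off
  metab_offset_hz(metab, name, field) + as.vector(b0) - carrier_hz
}

## Effective flip weight per voxel from the pulse's Bloch spectral profile
## at slice center, linearly interpolated at the demodulated offsets.
excitation_weights <- function(pulse, df_vox, field) {
  rng <- range(df_vox)
  fgrid <- seq(rng[1] - 20, rng[2] + 20, length.out = 161L)
  prof <- simulate_profile(pulse, 0, fgrid, field)
  flip_eff <- atan2(Mod(prof$mxy[1, ]), prof$mz[1, ]) * 180 / pi
  w <- stats::approx(fgrid, flip_eff, df_vox)$y / pulse$flip
  pmin(pmax(w, 0), 1.5)
}

#' Acquire one metabolite-specific flyback EPI frame
#'
#' Applies the SSRF pulse once (consuming magnetization according to the
#' pulse's Bloch profile evaluated at each voxel's metabolite + B0 offset),
#' then samples the discrete Fourier transform of the excited transverse
#' map along the flyback trajectory with per-sample off-resonance phase
#' accrual and T2 decay, plus complex white Gaussian noise.
#'
#' @param phantom A `digital_phantom`.
#' @param state An `hp_state` (the pulse's metabolite must be present).
#' @param pulse A calibrated `ssrf_pulse` with `metabolite` set.
#' @param traj A `flyback_traj` (its geometry defines the image grid).
#' @param field,metab Field parameters and metabolite table.
#' @param noise_sigma Complex-Gaussian noise standard deviation per sample.
#' @param seed Seed for the noise draw.
#' @param carrier_hz Scanner carrier offset (see package conventions).
#' @param w Optional precomputed excitation weights (per voxel).
#' @return List with the `kspace_frame` (`samples` matrix, `metabolite`,
#'   `t_acq`, `noise_sigma`, bandwidth info) and the consumed `state`.
#' @export
acquire_epi_frame <- function(phantom, state, pulse, traj,
                              field = field_params(),
                              metab = metabolite_table(),
                              noise_sigma = 0, seed = NULL,
                              carrier_hz = 0, w = NULL) {
  name <- pulse$metabolite
  if (is.null(name) || !name %in% colnames(state$mz))
    stop("pulse metabolite absent from state", call. = FALSE)
  if (!identical(dim(phantom$b0_map),
                 c(phantom$grid$matrix[1], phantom$grid$matrix[2])))
    stop("phantom/geometry mismatch", call. = FALSE)
  df_vox <- voxel_offsets(phantom, metab, name, field, carrier_hz)
  if (is.null(w)) w <- excitation_weights(pulse, df_vox, field)
  ex <- apply_rf_consumption(state, name, pulse$flip, w)
  state <- ex$state
  sig <- ex$signal
  idx <- which(sig != 0)
  nr <- traj$geom$matrix[1]; nl <- traj$geom$matrix[2]
  tt <- as.vector(traj$t_ms) * 1e-3
  S <- complex(length(tt))
  if (length(idx)) {
    nx <- phantom$grid$matrix[1]
    xv <- grid_coords_cm(nx, phantom$grid$fov[1])[((idx - 1) %% nx) + 1]
    yv <- grid_coords_cm(phantom$grid$matrix[2],
                         phantom$grid$fov[2])[((idx - 1) %/% nx) + 1]
    kxx <- rep(traj$kx, times = nl)
    kyy <- rep(traj$ky, each = nr)
    enc <- exp(-2i * pi * (outer(kxx, xv) + outer(kyy, yv)))
    phs <- exp(2i * pi * outer(tt, df_vox[idx]))
    t2 <- met_row(metab, name)$t2
    S <- as.vector((enc * phs) %*% sig[idx]) * exp(-tt / t2)
  }
  if (noise_sigma > 0) {
    if (is.null(seed)) stop("seed required when noise_sigma > 0",
                            call. = FALSE)
    S <- S + with_seed(seed, complex(real = stats::rnorm(length(S)),
                                     imaginary = stats::rnorm(length(S)))) *
      noise_sigma
  }
  frame <- structure(list(samples = matrix(S, nr, nl), metabolite = name,
                          t_acq = state$t, noise_sigma = noise_sigma,
                          bw_read = traj$bw_read, bw_phase = traj$bw_phase,
                          geom = traj$geom,
                          pulse_offset_hz = pulse$center_offset_hz,
                          flip = pulse$flip),
                     class = "kspace_frame")
  list(frame = frame, state = state)
}

#' Run the dynamic alternating pyruvate/lactate EPI protocol
#'
#' Acquires alternating metabolite-specific frames (pyruvate first) at each
#' schedule interval, evolving the hyperpolarized state (relaxation,
#' exchange, inflow) between acquisitions. The state is first evolved
#' through the schedule's start delay.
#'
#' @param phantom,state,field,metab See [acquire_epi_frame()].
#' @param schedule A [protocol_schedule()].
#' @param pulses Named list of calibrated pulses (names matching the
#'   schedule's flips).
#' @param traj A `flyback_traj`.
#' @param noise_sigma,seed Noise level and seed (per-frame seeds derived).
#' @param carrier_hz Scanner carrier offset (Hz).
#' @return List with `frames` (list of `kspace_frame`, length
#'   `2 * n_frames`) and the final `state`.
#' @export
run_dynamic_epi <- function(phantom, state, schedule, pulses, traj,
                            field = field_params(),
                            metab = metabolite_table(),
                            noise_sigma = 0, seed = 1L, carrier_hz = 0) {
  stopifnot(inherits(schedule, "protocol_schedule"))
  mets <- names(schedule$flips)
  stopifnot(all(mets %in% names(pulses)))
  if (state$t < schedule$start_delay)
    state <- evolve_hp_state(state, schedule$start_delay - state$t)
  ## excitation weights are static (B0 and carrier fixed): compute once
  ws <- lapply(mets, function(nm)
    excitation_weights(pulses[[nm]],
                       voxel_offsets(phantom, metab, nm, field, carrier_hz),
                       field))
  names(ws) <- mets
  frames <- vector("list", 2L * schedule$n_frames)
  k <- 0L
  for (i in seq_len(schedule$n_frames)) {
    for (j in seq_along(mets)) {
      nm <- mets[j]
      acq <- acquire_epi_frame(phantom, state, pulses[[nm]], traj, field,
                               metab, noise_sigma,
                               seed = seed + 131L * k, carrier_hz,
                               w = ws[[nm]])
      k <- k + 1L
      frames[[k]] <- acq$frame
      state <- evolve_hp_state(acq$state, schedule$interval / length(mets))
    }
  }
  list(frames = frames, state = state)
}

csi_encode_grid <- function(geom) {
  nr <- geom$matrix[1]; nl <- geom$matrix[2]
  fov_cm <- geom$fov / 10
  list(kx = (seq_len(nr) - 1 - nr %/% 2) / fov_cm[1],
       ky = (seq_len(nl) - 1 - nl %/% 2) / fov_cm[2])
}

#' Acquire one dynamic CSI frame (one phase encode per excitation)
#'
#' Chemical shift imaging: each of the `prod(matrix)` phase-encode steps is
#' preceded by one non-selective hard excitation that consumes
#' `cos(flip)` of every hyperpolarized metabolite's longitudinal
#' magnetization; the FID for each encode is the phase-encoded sum over
#' voxels of all species (tissue metabolites plus the thermal urea vial,
#' which recovers fully between excitations) with T2* decay. The state
#' evolves by TR between excitations, so one frame spans
#' `prod(matrix) * TR` seconds.
#'
#' @param phantom,state,field,metab Phantom, state, constants.
#' @param geom CSI geometry (default 8 x 8 over the 80 mm FOV).
#' @param flip Hard-pulse flip (degrees).
#' @param sw Spectral bandwidth (Hz).
#' @param np Complex spectral points per FID.
#' @param tr_ms Repetition time per excitation (ms).
#' @param t2star_ms Effective transverse decay of the FIDs (ms).
#' @param noise_sigma,seed Complex noise per FID sample and seed.
#' @param carrier_hz Scanner carrier offset (Hz).
#' @return List with a `spectral_grid` (`fids` array `np x nr x nl`, `sw`,
#'   `np`, `tr_ms`, `flip`, `t_acq`) and the consumed `state`.
#' @export
acquire_csi_frame <- function(phantom, state,
                              geom = geometry2d(c(8L, 8L), c(80, 80), 20),
                              flip = 10, sw = 25000, np = 2048, tr_ms = 82,
                              t2star_ms = phantom$params$t2star_ms %||% 30,
                              field = field_params(),
                              metab = metabolite_table(),
                              noise_sigma = 0, seed = 1L, carrier_hz = 0) {
  stopifnot(np >= 1, sw > 0)
  nr <- geom$matrix[1]; nl <- geom$matrix[2]
  nenc <- nr * nl
  enc <- csi_encode_grid(geom)
  nx <- phantom$grid$matrix[1]; nyp <- phantom$grid$matrix[2]
  xv_all <- grid_coords_cm(nx, phantom$grid$fov[1])
  yv_all <- grid_coords_cm(nyp, phantom$grid$fov[2])
  body_idx <- which(phantom$body)
  vial_idx <- which(phantom$masks$urea_vial)
  mets <- colnames(state$mz)
  tt <- (seq_len(np) - 1) / sw
  decay <- exp(-tt / (t2star_ms / 1000))
  ## spectral basis: one column per (voxel, species), static across encodes
  cols_df <- c(unlist(lapply(mets, function(nm)
    voxel_offsets(phantom, metab, nm, field, carrier_hz)[body_idx])),
    rep(metab_offset_hz(metab, "urea", field) - carrier_hz,
        length(vial_idx)))
  E <- exp(2i * pi * outer(tt, cols_df)) * decay
  vox_idx <- c(rep(body_idx, length(mets)), vial_idx)
  xs <- xv_all[((vox_idx - 1) %% nx) + 1]
  ys <- yv_all[((vox_idx - 1) %/% nx) + 1]
  kxx <- rep(enc$kx, times = nl)
  kyy <- rep(enc$ky, each = nr)
  ## per-encode amplitudes: consumption + evolution between TRs
  A <- matrix(0 + 0i, length(vox_idx), nenc)
  sinf <- sin(flip * pi / 180)
  for (e in seq_len(nenc)) {
    sig <- numeric(0)
    for (nm in mets) {
      exc <- apply_rf_consumption(state, nm, flip, 1)
      state <- exc$state
      sig <- c(sig, exc$signal[body_idx])
    }
    sig <- c(sig, rep(phantom$urea_amp * sinf, length(vial_idx)))
    A[, e] <- sig * exp(-2i * pi * (kxx[e] * xs + kyy[e] * ys))
    state <- evolve_hp_state(state, tr_ms / 1000)
  }
  fids <- E %*% A
  if (noise_sigma > 0)
    fids <- fids + with_seed(seed,
      complex(real = stats::rnorm(length(fids)),
              imaginary = stats::rnorm(length(fids)))) * noise_sigma
  sg <- structure(list(fids = array(fids, c(np, nr, nl)), sw = sw, np = np,
                       tr_ms = tr_ms, flip = flip, geom = geom,
                       t_acq = state$t, noise_sigma = noise_sigma,
                       carrier_hz = carrier_hz),
                  class = "spectral_grid")
  list(grid = sg, state = state)
}

#' Acquire the slab pre-scan carbon spectrum
#'
#' Single slab-selective low-flip excitation: one FID summing every in-slab
#' voxel's species (hyperpolarized metabolites plus the thermal urea vial),
#' used by the automated center-frequency calibration. The in-slab
#' hyperpolarized magnetization is consumed by `cos(flip)`.
#'
#' @param phantom,state,field,metab Phantom, state, constants.
#' @param slab List with `axis` (1 or 2) and `range_mm` (`c(lo, hi)`,
#'   FOV-centered coordinates): voxels whose center falls inside are
#'   included. The default spans liver, kidneys and the urea vial but
#'   excludes the chest.
#' @param flip Excitation flip (degrees).
#' @param sw,np Spectral bandwidth (Hz) and complex points.
#' @param t2star_ms FID decay constant (ms).
#' @param noise_sigma,seed Complex noise level and seed.
#' @param carrier_hz Scanner carrier offset (Hz).
#' @return List with a single-FID `spectral_grid` (`fids` of dim
#'   `np x 1 x 1`) and the consumed `state`.
#' @export
acquire_slab_spectrum <- function(phantom, state,
                                  slab = list(axis = 2, range_mm = c(-40, 15)),
                                  flip = 5, sw = 10000, np = 2048,
                                  t2star_ms = phantom$params$t2star_ms %||% 30,
                                  field = field_params(),
                                  metab = metabolite_table(),
                                  noise_sigma = 0, seed = 1L,
                                  carrier_hz = 0) {
  nx <- phantom$grid$matrix[1]; nyp <- phantom$grid$matrix[2]
  coord <- if (slab$axis == 1)
    rep(grid_coords_cm(nx, phantom$grid$fov[1]) * 10, times = nyp)
  else rep(grid_coords_cm(nyp, phantom$grid$fov[2]) * 10, each = nx)
  in_slab <- coord >= slab$range_mm[1] & coord <= slab$range_mm[2]
  body_idx <- which(phantom$body & matrix(in_slab, nx, nyp))
  vial_idx <- which(phantom$masks$urea_vial & matrix(in_slab, nx, nyp))
  if (!length(body_idx) && !length(vial_idx))
    stop("empty slab: no phantom voxels selected", call. = FALSE)
  tt <- (seq_len(np) - 1) / sw
  decay <- exp(-tt / (t2star_ms / 1000))
  fid <- complex(np)
  sinf <- sin(flip * pi / 180)
  for (nm in colnames(state$mz)) {
    w <- as.numeric(matrix(in_slab, nx, nyp))   # slab weight, 0 or 1
    exc <- apply_rf_consumption(state, nm, flip, w)
    state <- exc$state
    idx <- body_idx
    if (length(idx)) {
      df <- voxel_offsets(phantom, metab, nm, field, carrier_hz)[idx]
      amp <- exc$signal[idx]
      fid <- fid + as.vector(exp(2i * pi * outer(tt, df)) %*% amp)
    }
  }
  if (length(vial_idx)) {
    df_u <- metab_offset_hz(metab, "urea", field) - carrier_hz
    fid <- fid + length(vial_idx) * phantom$urea_amp * sinf *
      exp(2i * pi * tt * df_u)
  }
  fid <- fid * decay
  if (noise_sigma > 0)
    fid <- fid + with_seed(seed,
      complex(real = stats::rnorm(np),
              imaginary = stats::rnorm(np))) * noise_sigma
  sg <- structure(list(fids = array(fid, c(np, 1L, 1L)), sw = sw, np = np,
                       tr_ms = NA_real_, flip = flip, geom = phantom$grid,
                       t_acq = state$t, noise_sigma = noise_sigma,
                       carrier_hz = carrier_hz),
                  class = "spectral_grid")
  list(spectrum = sg, state = state)
}

#' Emulate the swept-frequency measurement of a pulse profile
#'
#' Reproduces the 1D profile-measurement experiment: the pulse center
#' frequency is stepped across a sweep range while exciting an on-resonance
#' long 1D water phantom; after each excitation the spatial projection is
#' read out (finite k-space sampling and magnitude reconstruction along the
#' excitation-gradient axis). The assembled (position x frequency) magnitude
#' map is the "measured" counterpart of [simulate_profile()]: a spin at
#' offset `-d` sees the same excitation as an on-resonance spin under a
#' pulse shifted by `+d`, so sweep step `d` fills the column at `f = -d`.
#'
#' @param pulse An `ssrf_pulse`.
#' @param sweep `c(lo, hi)` sweep range of the pulse center frequency (Hz).
#' @param n_steps Number of sweep steps.
#' @param phantom_1d List: `length_cm` of the uniform water cylinder,
#'   `fov_cm` and `n_read` of the projection readout.
#' @param field A [field_params()] object.
#' @return A `mag_profile` (magnitude only) on the readout's spatial grid
#'   and the sweep's frequency grid.
#' @export
measure_pulse_profile <- function(pulse, sweep = c(-600, 600),
                                  n_steps = 121L,
                                  phantom_1d = list(length_cm = 6,
                                                    fov_cm = 9, n_read = 64L),
                                  field = field_params()) {
  stopifnot(n_steps >= 2L)
  n_read <- phantom_1d$n_read
  fovz <- phantom_1d$fov_cm
  nz_fine <- 4L * n_read
  z_fine <- (seq_len(nz_fine) - 1 - nz_fine %/% 2) * (fovz / nz_fine)
  dens <- as.numeric(abs(z_fine) <= phantom_1d$length_cm / 2)
  z_img <- (seq_len(n_read) - 1 - n_read %/% 2) * (fovz / n_read)
  kz <- (seq_len(n_read) - 1 - n_read %/% 2) / fovz
  enc <- exp(-2i * pi * outer(kz, z_fine))
  dec <- exp(2i * pi * outer(z_img, kz))
  d_steps <- seq(sweep[1], sweep[2], length.out = n_steps)
  mag <- matrix(0, n_read, n_steps)
  for (s in seq_along(d_steps)) {
    p <- shift_pulse_center(pulse, pulse$center_offset_hz + d_steps[s])
    prof <- simulate_profile(p, z_fine, 0, field)
    proj <- prof$mxy[, 1] * dens
    img <- (dec %*% (enc %*% proj)) / nz_fine
    mag[, n_steps - s + 1] <- Mod(img)   # step d fills column f = -d
  }
  f_grid <- rev(-d_steps)
  structure(list(z = z_img, f = f_grid, mxy = mag + 0i,
                 mz = matrix(sqrt(pmax(0, 1 - mag^2)), nrow(mag)), m0 = 1),
            class = "mag_profile")
}
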