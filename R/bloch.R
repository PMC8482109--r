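#' Bloch-simulate the spectral-spatial profile of a pulse
#'
#' Hard-pulse (piecewise-constant) Bloch simulation: for every point of the
#' (position, frequency-offset) grid the magnetization, starting from
#' equilibrium `m0`, is composed through one exact rotation per waveform
#' sample about the effective field (B1 sample; gradient x position plus
#' off-resonance along z). No relaxation is applied during the pulse
#' (durations are far below T1/T2). Since the waveform is piecewise
#' constant, each per-sample rotation is the exact solution for that
#' interval.
#'
#' Rotating-frame convention: positive off-resonance rotates transverse
#' magnetization counterclockwise about +z (right-handed rotations about the
#' effective-field axis).
#'
#' @param pulse An `ssrf_pulse` (uses its current, offset-modulated RF).
#' @param z_grid Spatial positions (cm), strictly increasing.
#' @param f_grid Frequency offsets (Hz) relative to the scanner carrier,
#'   strictly increasing.
#' @param field A [field_params()] object.
#' @param m0 Initial longitudinal magnetization.
#' @param subsample Integer: split every waveform sample into this many
#'   equal sub-samples (discretization-convergence checks).
#' @return An object of class `mag_profile`: `z`, `f`, complex `mxy` and
#'   real `mz` matrices of dimension `length(z) x length(f)`, and `m0`.
#' @export
simulate_profile <- function(pulse, z_grid, f_grid, field = field_params(),
                             m0 = 1, subsample = 1L) {
  stopifnot(length(pulse$rf) > 0, length(z_grid) > 0, length(f_grid) > 0,
            subsample >= 1L)
  if (is.unsorted(z_grid, strictly = TRUE) && length(z_grid) > 1)
    stop("z_grid must be strictly increasing", call. = FALSE)
  if (is.unsorted(f_grid, strictly = TRUE) && length(f_grid) > 1)
    stop("f_grid must be strictly increasing", call. = FALSE)
  rf <- pulse$rf
  grad <- pulse$grad
  dt <- pulse$dwell * 1e-6
  if (subsample > 1L) {
    rf <- rep(rf, each = subsample)
    grad <- rep(grad, each = subsample)
    dt <- dt / subsample
  }
  nz <- length(z_grid); nf <- length(f_grid)
  Z <- rep(field$gamma * z_grid, times = nf)   # Hz per (G/cm)
  Fv <- rep(f_grid, each = nz)
  mx <- numeric(nz * nf); my <- numeric(nz * nf)
  mz <- rep(as.numeric(m0), nz * nf)
  w <- 2 * pi * dt
  bx_all <- field$gamma * Re(rf)
  by_all <- field$gamma * Im(rf)
  for (s in seq_along(rf)) {
    bz <- grad[s] * Z + Fv
    bx <- bx_all[s]; by <- by_all[s]
    if (bx == 0 && by == 0) {
      phi <- w * bz
      cp <- cos(phi); sp <- sin(phi)
      tmp <- mx * cp - my * sp
      my <- mx * sp + my * cp
      mx <- tmp
    } else {
      b <- sqrt(bx * bx + by * by + bz * bz)
      phi <- w * b
      nx <- bx / b; ny <- by / b; nzx <- bz / b
      cp <- cos(phi); sp <- sin(phi); k1 <- 1 - cp
      ndm <- nx * mx + ny * my + nzx * mz
      cxv <- ny * mz - nzx * my
      cyv <- nzx * mx - nx * mz
      czv <- nx * my - ny * mx
      mx2 <- mx * cp + cxv * sp + nx * ndm * k1
      my2 <- my * cp + cyv * sp + ny * ndm * k1
      mz  <- mz * cp + czv * sp + nzx * ndm * k1
      mx <- mx2; my <- my2
    }
  }
  structure(list(z = z_grid, f = f_grid,
                 mxy = matrix(complex(real = mx, imaginary = my), nz, nf),
                 mz = matrix(mz, nz, nf), m0 = m0),
            class = "mag_profile")
}

#' @export
print.mag_profile <- function(x, ...) {
  cat(sprintf("<mag_profile> %d z x %d f grid, max |Mxy| = %.4f\n",
              length(x$z), length(x$f), max(Mod(x$mxy))))
  invisible(x)
}

nearest_idx <- function(grid, v) which.min(abs(grid - v))

#' Flip angle at a point of a magnetization profile
#'
#' @param profile A `mag_profile`.
#' @param z Position (cm); nearest grid point is used.
#' @param f Frequency offset (Hz); nearest grid point is used.
#' @return Flip angle in degrees, `atan2(|Mxy|, Mz)`.
#' @export
measure_flip <- function(profile, z = 0, f = 0) {
  iz <- nearest_idx(profile$z, z)
  jf <- nearest_idx(profile$f, f)
  atan2(Mod(profile$mxy[iz, jf]), profile$mz[iz, jf]) * 180 / pi
}

band_cols <- function(profile, band) {
  if (band[1] < min(profile$f) - 1e-9 || band[2] > max(profile$f) + 1e-9)
    stop("band [", band[1], ", ", band[2], "] Hz outside the frequency grid",
         call. = FALSE)
  which(profile$f >= band[1] - 1e-9 & profile$f <= band[2] + 1e-9)
}

#' Spectral band metrics of a simulated profile
#'
#' Evaluates a profile at one spatial position against a passband/stopband
#' specification. The excitation fraction is `|Mxy| / sin(nominal flip)`;
#' passband ripple is the maximum of `|fraction - 1|` over the passband,
#' stopband ripple the maximum fraction over each stopband. The passband
#' half-width is the largest `h` such that the ripple criterion holds at
#' every offset within `h` of the passband center, with the criterion
#' crossing located by linear interpolation between grid points.
#'
#' @param profile A `mag_profile`.
#' @param z Position (cm) at which to evaluate (nearest grid point).
#' @param passband `c(lo, hi)` passband edges (Hz).
#' @param stopbands List of `c(lo, hi)` stopband edges (Hz).
#' @param nominal_flip Nominal flip angle (degrees).
#' @param criterion Ripple criterion used for the half-width measurement.
#' @return List: `passband_ripple`, `passband_mean`, `stopband_ripple`
#'   (vector), `stopband_mean` (vector), `pass_halfwidth_hz`, `max_deviation`
#'   (worst pass/stop deviation as an excitation fraction).
#' @export
measure_band_metrics <- function(profile, z = 0, passband, stopbands = list(),
                                 nominal_flip, criterion = 0.01) {
  iz <- nearest_idx(profile$z, z)
  frac <- Mod(profile$mxy[iz, ]) / sin(nominal_flip * pi / 180)
  jp <- band_cols(profile, passband)
  pass_ripple <- max(abs(frac[jp] - 1))
  pass_mean <- mean(frac[jp])
  stop_ripple <- vapply(stopbands, function(b) max(frac[band_cols(profile, b)]),
                        numeric(1))
  stop_mean <- vapply(stopbands, function(b) mean(frac[band_cols(profile, b)]),
                      numeric(1))
  center <- mean(passband)
  dev <- abs(frac - 1)
  jc <- nearest_idx(profile$f, center)
  halfwidth <- 0
  if (dev[jc] <= criterion) {
    cross <- function(idx_seq) {
      h <- Inf
      prev <- jc
      for (j in idx_seq) {
        if (dev[j] > criterion) {
          ## linear interpolation of the criterion crossing
          w <- (criterion - dev[prev]) / (dev[j] - dev[prev])
          return(abs(profile$f[prev] + w * (profile$f[j] - profile$f[prev]) -
                       center))
        }
        prev <- j
      }
      abs(profile$f[prev] - center)
    }
    up <- if (jc < length(frac)) cross(seq(jc + 1L, length(frac))) else 0
    dn <- if (jc > 1L) cross(seq(jc - 1L, 1L)) else 0
    halfwidth <- min(up, dn)
  }
  list(passband_ripple = pass_ripple, passband_mean = pass_mean,
       stopband_ripple = stop_ripple, stopband_mean = stop_mean,
       pass_halfwidth_hz = halfwidth,
       max_deviation = max(pass_ripple, stop_ripple, 0))
}

bilinear_interp <- function(xg, yg, Z, x, y) {
  if (min(x) < min(xg) - 1e-9 || max(x) > max(xg) + 1e-9 ||
      min(y) < min(yg) - 1e-9 || max(y) > max(yg) + 1e-9)
    stop("regrid target outside the measured range (no extrapolation)",
         call. = FALSE)
  ix <- pmin(pmax(findInterval(x, xg), 1L), length(xg) - 1L)
  iy <- pmin(pmax(findInterval(y, yg), 1L), length(yg) - 1L)
  if (length(xg) == 1L) ix <- rep(1L, length(x))
  if (length(yg) == 1L) iy <- rep(1L, length(y))
  wx <- if (length(xg) > 1L) (x - xg[ix]) / (xg[ix + 1L] - xg[ix]) else 0 * x
  wy <- if (length(yg) > 1L) (y - yg[iy]) / (yg[iy + 1L] - yg[iy]) else 0 * y
  out <- matrix(0, length(x), length(y))
  for (j in seq_along(y)) {
    j0 <- iy[j]; j1 <- min(j0 + 1L, ncol(Z)); v <- wy[j]
    col0 <- Z[, j0] * (1 - v) + Z[, j1] * v
    out[, j] <- col0[ix] * (1 - wx) +
      col0[pmin(ix + 1L, nrow(Z))] * wx
  }
  out
}

#' Regrid a measured profile onto target grids
#'
#' Bilinear interpolation of the magnitude `|Mxy|` (and `Mz`) onto the
#' target position/frequency grids, as used to compare measured excitation
#' profiles to simulated ones. Requests outside the measured range raise a
#' range error; there is no extrapolation.
#'
#' @param measured A `mag_profile`.
#' @param target_z Target positions (cm).
#' @param target_f Target frequency offsets (Hz).
#' @return A `mag_profile` on the target grids; `mxy` carries the
#'   interpolated magnitude (zero phase).
#' @export
regrid_profile <- function(measured, target_z, target_f) {
  mag <- bilinear_interp(measured$z, measured$f, Mod(measured$mxy),
                         target_z, target_f)
  mz <- bilinear_interp(measured$z, measured$f, measured$mz,
                        target_z, target_f)
  structure(list(z = target_z, f = target_f,
                 mxy = mag + 0i, mz = mz, m0 = measured$m0),
            class = "mag_profile")
}
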