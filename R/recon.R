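## Centered 2D FFT helpers. Image convention: voxel centers, 0-based index
## i at position (i - n/2)*dx, DC at index n/2 (even matrices); sample c
## holds kx = (c - n/2)*dk. fftshift moves the DC-centered layout to the
## 0-first layout expected by stats::fft and back.
fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((n1 %/% 2 + 1):n1, 1:(n1 %/% 2)),
    c((n2 %/% 2 + 1):n2, 1:(n2 %/% 2)), drop = FALSE]
}
ifftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  s1 <- ceiling(n1 / 2); s2 <- ceiling(n2 / 2)
  m[c((s1 + 1):n1, 1:s1)[seq_len(n1)],
    c((s2 + 1):n2, 1:s2)[seq_len(n2)], drop = FALSE]
}

fft2 <- function(m, inverse = FALSE) {
  stats::fft(m, inverse = inverse)
}

#' Reconstruct one EPI k-space frame
#'
#' Plain 2D inverse discrete Fourier transform of the complete Cartesian
#' flyback grid, DC at the image center.
#'
#' @param frame A `kspace_frame` (or a bare complex matrix).
#' @return Complex image matrix of the same dimensions.
#' @export
recon_epi_frame <- function(frame) {
  S <- if (inherits(frame, "kspace_frame")) frame$samples else frame
  if (!is.matrix(S) || anyNA(S))
    stop("incomplete k-space grid", call. = FALSE)
  n <- length(S)
  fftshift2(fft2(ifftshift2(S), inverse = TRUE)) / n
}

## forward counterpart (used by the shift correction and in tests)
forward_epi_frame <- function(img) {
  fftshift2(fft2(ifftshift2(img), inverse = FALSE))
}

#' Correct the chemical-shift displacement of an EPI image
#'
#' An off-resonance species acquires phase during the EPI readout and lands
#' displaced by `df/bw_read` of the FOV along the readout axis and
#' `df/bw_phase` along the phase-encode axis. The correction multiplies
#' k-space by the conjugate of that phase accrual
#' (`exp(-2i*pi*df*t(c,l))` with `t = c*dwell + l*esp`, centered indices),
#' i.e. a subvoxel-capable Fourier-domain translation that exactly undoes
#' the acquisition model's displacement for `df` equal to the
#' metabolite-minus-pulse-center offset.
#'
#' @param image Complex image matrix (read axis first).
#' @param df Frequency offset to correct (Hz).
#' @param traj The `flyback_traj` used for the acquisition (bandwidths).
#' @return The translated complex image.
#' @export
apply_chemshift_shift <- function(image, df, traj) {
  if (df == 0) return(image)
  nr <- nrow(image); nl <- ncol(image)
  K <- forward_epi_frame(image)
  ci <- (seq_len(nr) - 1 - nr %/% 2) / traj$bw_read
  li <- (seq_len(nl) - 1 - nl %/% 2) * traj$esp_ms / 1000
  ph <- exp(-2i * pi * df * outer(ci, li, `+`))
  recon_epi_frame(K * ph)
}

#' Exponentially apodize an FID
#'
#' Line-broadening convention: sample `n` is multiplied by
#' `exp(-pi * lb * n * dwell)`, which adds `lb` Hz to the full width at half
#' maximum of a Lorentzian line.
#'
#' @param fid Complex FID samples.
#' @param lb Line broadening (Hz), non-negative.
#' @param dwell Sample interval of the FID (s).
#' @return The apodized FID.
#' @export
apodize_fid <- function(fid, lb, dwell) {
  if (lb < 0) stop("negative line broadening", call. = FALSE)
  fid * exp(-pi * lb * (seq_along(fid) - 1) * dwell)
}

## centered spectral axis (Hz) of an np-point FID at bandwidth sw
spectral_axis <- function(np, sw) (seq_len(np) - 1 - np %/% 2) * sw / np

## magnitude spectrum with DC-centered axis; FID model e^{2i pi f t} peaks
## at +f on this axis
fid_spectrum <- function(fid) {
  n <- length(fid)
  sp <- stats::fft(fid)
  lo <- n %/% 2 + 1L + n %% 2L
  c(sp[lo:n], sp[1:(lo - 1L)])
}

## Rayleigh-consistent noise scale from a signal-free magnitude sample
rayleigh_sigma <- function(mag) stats::median(mag) / sqrt(log(4))

#' Reconstruct a CSI series into metabolite maps
#'
#' Per frame: 2D spatial inverse DFT across the phase encodes, exponential
#' apodization of every voxel FID, spectral FFT, magnitude; each
#' metabolite's map value is the peak height (maximum magnitude) within its
#' spectral window. Maps are reported in SNR units: peak height divided by
#' the noise scale estimated from the outer 10% of the spectral axis
#' (median-based Rayleigh-consistent estimator).
#'
#' @param grids A `spectral_grid` or list of them (one per time point).
#' @param lb Exponential line broadening (Hz).
#' @param metab Metabolite table.
#' @param windows Named list of `c(lo, hi)` spectral windows in Hz relative
#'   to the carrier; defaults to +/- `window_halfwidth_ppm` around each of
#'   pyruvate and lactate. Windows must be disjoint.
#' @param window_halfwidth_ppm Half-width of the default windows (ppm).
#' @param field Field parameters.
#' @param normalize `"snr"` (default) divides peak heights by the estimated
#'   noise scale; `"none"` returns raw peak heights (linear in the source
#'   amplitude, useful for noiseless quantitative checks).
#' @return A `metab_image_series`: per-metabolite list of `nr x nl x T`
#'   arrays in SNR units, `timestamps`, `geometry`.
#' @export
recon_csi <- function(grids, lb = 12, metab = metabolite_table(),
                      windows = NULL, window_halfwidth_ppm = 1.5,
                      field = field_params(),
                      normalize = c("snr", "none")) {
  normalize <- match.arg(normalize)
  if (inherits(grids, "spectral_grid")) grids <- list(grids)
  g1 <- grids[[1]]
  if (is.null(windows)) {
    hw <- ppm_to_hz(window_halfwidth_ppm, field)
    windows <- lapply(c(pyruvate = "pyruvate", lactate = "lactate"),
                      function(nm) {
                        c0 <- metab_offset_hz(metab, nm, field) - g1$carrier_hz
                        c(c0 - hw, c0 + hw)
                      })
  }
  wn <- names(windows)
  for (i in seq_along(windows)) for (j in seq_len(i - 1L)) {
    if (windows[[i]][1] < windows[[j]][2] && windows[[j]][1] < windows[[i]][2])
      stop("overlapping metabolite windows: ", wn[i], " and ", wn[j],
           call. = FALSE)
  }
  np <- g1$np; nr <- g1$geom$matrix[1]; nl <- g1$geom$matrix[2]
  fax <- spectral_axis(np, g1$sw)
  if (min(vapply(windows, min, 0)) < fax[1] ||
      max(vapply(windows, max, 0)) > fax[np])
    stop("spectral axis does not cover the metabolite windows",
         call. = FALSE)
  outer_bins <- c(seq_len(ceiling(np * 0.05)),
                  np - seq_len(ceiling(np * 0.05)) + 1L)
  dwell <- 1 / g1$sw
  out <- lapply(windows, function(w) array(0, c(nr, nl, length(grids))))
  ts <- numeric(length(grids))
  for (tix in seq_along(grids)) {
    g <- grids[[tix]]
    stopifnot(g$np == np)
    ## spatial inverse DFT over the encode dimensions (centered convention)
    fids <- matrix(g$fids, np, nr * nl)
    W1 <- idft_matrix(nr); W2 <- idft_matrix(nl)
    sp <- array(t(fids), c(nr, nl, np))
    for (p in seq_len(np))
      sp[, , p] <- W1 %*% sp[, , p] %*% t(W2)
    apod <- exp(-pi * lb * (seq_len(np) - 1) * dwell)
    mag <- array(0, c(nr, nl, np))
    for (ix in seq_len(nr)) for (iy in seq_len(nl)) {
      v <- fid_spectrum(sp[ix, iy, ] * apod)
      mag[ix, iy, ] <- Mod(v)
    }
    sig <- if (normalize == "snr")
      rayleigh_sigma(as.vector(mag[, , outer_bins])) else 1
    if (sig <= 0) sig <- 1
    for (nm in wn) {
      sel <- which(fax >= windows[[nm]][1] & fax <= windows[[nm]][2])
      out[[nm]][, , tix] <- apply(mag[, , sel, drop = FALSE], c(1, 2), max) /
        sig
    }
    ts[tix] <- g$t_acq
  }
  structure(list(images = out, timestamps = ts,
                 geometry = geometry2d(c(nr, nl), g1$geom$fov,
                                       g1$geom$slice_thickness),
                 units = "snr"),
            class = "metab_image_series")
}

## centered inverse DFT matrix mapping k indices to image indices
idft_matrix <- function(n) {
  idx <- seq_len(n) - 1 - n %/% 2
  exp(2i * pi * outer(idx, idx) / n) / n
}

#' Reconstruct a dynamic EPI frame series into metabolite maps
#'
#' Inverse FFT per frame, chemical-shift displacement correction with each
#' metabolite's reconstruction shift, magnitude, and SNR normalization by
#' the per-voxel image-domain noise level implied by the acquisition noise
#' (`noise_sigma / sqrt(n_voxels)`; unit scale when noiseless).
#'
#' @param frames List of `kspace_frame` (mixed metabolites allowed).
#' @param traj The `flyback_traj` used in the acquisition.
#' @param recon_shifts Named numeric: correction frequency (Hz) per
#'   metabolite, e.g. from [compute_offsets()]. Missing names get 0.
#' @return A `metab_image_series` (per-metabolite arrays, SNR units).
#' @export
recon_epi_series <- function(frames, traj, recon_shifts = c()) {
  mets <- unique(vapply(frames, function(f) f$metabolite, character(1)))
  nr <- traj$geom$matrix[1]; nl <- traj$geom$matrix[2]
  out <- list(); ts <- list()
  for (nm in mets) {
    sel <- Filter(function(f) identical(f$metabolite, nm), frames)
    arr <- array(0, c(nr, nl, length(sel)))
    tv <- numeric(length(sel))
    df <- if (nm %in% names(recon_shifts)) recon_shifts[[nm]] else 0
    for (i in seq_along(sel)) {
      img <- recon_epi_frame(sel[[i]])
      img <- apply_chemshift_shift(img, df, traj)
      sig <- sel[[i]]$noise_sigma / sqrt(nr * nl)
      if (sig <= 0) sig <- 1
      arr[, , i] <- Mod(img) / sig
      tv[i] <- sel[[i]]$t_acq
    }
    out[[nm]] <- arr; ts[[nm]] <- tv
  }
  structure(list(images = out, timestamps = ts[[1]],
                 geometry = traj$geom, units = "snr"),
            class = "metab_image_series")
}

#' @export
print.metab_image_series <- function(x, ...) {
  cat(sprintf("<metab_image_series> %s; %d x %d, %d time points (%s units)\n",
              paste(names(x$images), collapse = ", "),
              x$geometry$matrix[1], x$geometry$matrix[2],
              dim(x$images[[1]])[3], x$units))
  invisible(x)
}

#' Downsample a phantom-resolution mask to an image grid
#'
#' @param mask Logical matrix on the fine grid.
#' @param geom_to Target [geometry2d()] (same FOV assumed).
#' @param min_frac Minimum fraction of fine voxels inside for a coarse voxel
#'   to be included.
#' @return Logical matrix on the coarse grid.
#' @export
downsample_mask <- function(mask, geom_to, min_frac = 0.5) {
  nf <- dim(mask)
  nc <- geom_to$matrix
  fx <- nf[1] / nc[1]; fy <- nf[2] / nc[2]
  out <- matrix(FALSE, nc[1], nc[2])
  for (i in seq_len(nc[1])) for (j in seq_len(nc[2])) {
    xi <- floor((i - 1) * fx) + seq_len(ceiling(fx))
    yi <- floor((j - 1) * fy) + seq_len(ceiling(fy))
    xi <- xi[xi <= nf[1]]; yi <- yi[yi <= nf[2]]
    out[i, j] <- mean(mask[xi, yi]) >= min_frac
  }
  out
}

#' Extract per-ROI, per-metabolite time curves from an image series
#'
#' @param series A `metab_image_series`.
#' @param masks Named list of logical matrices on the series geometry.
#' @return A data.frame with columns `roi`, `metabolite`, `t`, `value`
#'   (mean SNR over the mask at each time point).
#' @export
extract_roi_curves <- function(series, masks) {
  nr <- series$geometry$matrix[1]; nl <- series$geometry$matrix[2]
  res <- list()
  for (rn in names(masks)) {
    m <- masks[[rn]]
    if (!identical(dim(m), c(nr, nl)))
      stop("mask ", rn, " does not match the series geometry", call. = FALSE)
    if (!any(m)) stop("empty mask: ", rn, call. = FALSE)
    for (nm in names(series$images)) {
      arr <- series$images[[nm]]
      vals <- apply(arr, 3, function(im) mean(im[m]))
      res[[length(res) + 1L]] <- data.frame(
        roi = rn, metabolite = nm, t = series$timestamps, value = vals,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}
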