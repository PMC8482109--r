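#' Export a pulse as plain-text waveforms with a JSON header
#'
#' Writes `<name>_rf.txt` (two columns: magnitude in gauss, phase in
#' degrees, 9 significant digits), `<name>_grad.txt` (one column, G/cm) and
#' `<name>_header.json` (dwell, duration, flip, B1 peak, center offset,
#' sub-pulse count). [read_pulse_waveform()] round-trips the arrays at the
#' printed precision.
#'
#' @param pulse An `ssrf_pulse`.
#' @param dir Output directory (created if missing).
#' @param name File stem.
#' @return Invisibly, the three file paths.
#' @export
write_pulse_waveform <- function(pulse, dir, name = pulse$metabolite %||% "pulse") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rf_path <- file.path(dir, paste0(name, "_rf.txt"))
  gr_path <- file.path(dir, paste0(name, "_grad.txt"))
  hd_path <- file.path(dir, paste0(name, "_header.json"))
  mag <- Mod(pulse$rf)
  ph <- Arg(pulse$rf) * 180 / pi
  writeLines(sprintf("%.9g %.9g", mag, ph), rf_path)
  writeLines(sprintf("%.9g", pulse$grad), gr_path)
  jsonlite::write_json(list(
    dwell_us = pulse$dwell, duration_ms = pulse$duration,
    flip_deg = pulse$flip, b1_peak = pulse$b1_peak,
    center_offset_hz = pulse$center_offset_hz,
    n_subpulses = pulse$n_subpulses,
    metabolite = pulse$metabolite %||% NA),
    hd_path, auto_unbox = TRUE, digits = I(17))
  invisible(c(rf_path, gr_path, hd_path))
}

#' Read a pulse exported by [write_pulse_waveform()]
#'
#' @param dir Directory containing the files.
#' @param name File stem.
#' @return An `ssrf_pulse` (waveforms and header fields; design metadata is
#'   not persisted).
#' @export
read_pulse_waveform <- function(dir, name) {
  rf_path <- file.path(dir, paste0(name, "_rf.txt"))
  hd_path <- file.path(dir, paste0(name, "_header.json"))
  gr_path <- file.path(dir, paste0(name, "_grad.txt"))
  for (p in c(rf_path, gr_path, hd_path))
    if (!file.exists(p)) stop("missing waveform file: ", p, call. = FALSE)
  rf_tab <- utils::read.table(rf_path, col.names = c("mag", "phase_deg"))
  if (anyNA(rf_tab))
    stop("parse error in ", rf_path, " near line ",
         which(apply(is.na(rf_tab), 1, any))[1], call. = FALSE)
  grad <- scan(gr_path, quiet = TRUE)
  hd <- jsonlite::read_json(hd_path, simplifyVector = TRUE)
  if (length(grad) != nrow(rf_tab))
    stop("rf/grad length mismatch between files", call. = FALSE)
  rf <- rf_tab$mag * exp(1i * rf_tab$phase_deg * pi / 180)
  off <- hd$center_offset_hz
  t_s <- (seq_along(rf) - 0.5) * hd$dwell_us * 1e-6
  structure(list(rf = rf, rf_base = rf * exp(-2i * pi * off * t_s),
                 grad = grad, dwell = hd$dwell_us,
                 duration = hd$duration_ms, flip = hd$flip_deg,
                 center_offset_hz = off, n_subpulses = hd$n_subpulses,
                 b1_peak = max(Mod(rf)),
                 metabolite = if (is.null(hd$metabolite) ||
                                  is.na(hd$metabolite)) NULL
                 else hd$metabolite),
            class = "ssrf_pulse")
}

#' Write a magnetization profile to JSON
#'
#' Grids plus the complex transverse and longitudinal magnetization at full
#' double precision; [read_profile_json()] restores the values bit-exactly.
#'
#' @param profile A `mag_profile`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile_json <- function(profile, path) {
  jsonlite::write_json(list(
    z = profile$z, f = profile$f,
    mxy_re = as.vector(Re(profile$mxy)), mxy_im = as.vector(Im(profile$mxy)),
    mz = as.vector(profile$mz), m0 = profile$m0),
    path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  nz <- length(x$z)
  as_mat <- function(v) matrix(as.numeric(v), nz, length(x$f))
  structure(list(z = x$z, f = x$f,
                 mxy = as_mat(x$mxy_re) + 1i * as_mat(x$mxy_im),
                 mz = as_mat(x$mz), m0 = x$m0),
            class = "mag_profile")
}

#' Serialize a digital phantom to JSON
#'
#' Masks (as 0/1), the B0 map, kinetic parameters and the seed; the
#' counterpart reader reconstructs an identical `digital_phantom`.
#'
#' @param phantom A `digital_phantom`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_phantom_json <- function(phantom, path) {
  jsonlite::write_json(list(
    matrix = phantom$grid$matrix, fov = phantom$grid$fov,
    slice_thickness = phantom$grid$slice_thickness,
    masks = lapply(phantom$masks, function(m) as.integer(m)),
    b0_map = as.vector(phantom$b0_map),
    chest_offset_hz = phantom$chest_offset_hz,
    body = as.integer(phantom$body),
    kpl = as.list(phantom$kpl), inflow_amp = as.list(phantom$inflow_amp),
    urea_amp = phantom$urea_amp, params = phantom$params,
    seed = phantom$seed),
    path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_phantom_json
#' @export
read_phantom_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  nr <- x$matrix[1]; nl <- x$matrix[2]
  as_m <- function(v, logical = FALSE) {
    m <- matrix(as.numeric(v), nr, nl)
    if (logical) m > 0 else m
  }
  structure(list(
    grid = geometry2d(x$matrix, x$fov, x$slice_thickness),
    masks = lapply(x$masks, as_m, logical = TRUE),
    b0_map = as_m(x$b0_map), chest_offset_hz = x$chest_offset_hz,
    body = as_m(x$body, logical = TRUE),
    kpl = unlist(x$kpl), inflow_amp = unlist(x$inflow_amp),
    urea_amp = x$urea_amp, params = x$params, seed = x$seed),
    class = "digital_phantom")
}

#' Write a metabolite image series as NIfTI files
#'
#' One 4D NIfTI per metabolite (time as the fourth dimension, voxel sizes
#' from the series geometry) plus a JSON sidecar with timestamps and units.
#'
#' @param series A `metab_image_series`.
#' @param dir Output directory.
#' @param stem File stem; files are `<stem>_<metabolite>.nii.gz`.
#' @return Invisibly, the written paths.
#' @export
write_image_series_nifti <- function(series, dir, stem = "metabolite") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- resolution(series$geometry)
  paths <- character(0)
  for (nm in names(series$images)) {
    arr <- series$images[[nm]]
    a4 <- array(arr, c(dim(arr)[1], dim(arr)[2], 1L, dim(arr)[3]))
    img <- RNifti::asNifti(a4)
    RNifti::pixdim(img) <- c(res[1], res[2],
                             series$geometry$slice_thickness, 1)
    p <- file.path(dir, sprintf("%s_%s.nii.gz", stem, nm))
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  side <- file.path(dir, paste0(stem, "_series.json"))
  jsonlite::write_json(list(metabolites = names(series$images),
                            timestamps = series$timestamps,
                            units = series$units),
                       side, auto_unbox = TRUE, digits = I(17))
  invisible(c(paths, side))
}
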