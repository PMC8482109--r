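#' Static field and RF hardware parameters
#'
#' Bundles the main magnet / transmit-chain constants used throughout the
#' package. The defaults describe a 4.7 T small-animal system operating
#' carbon-13 at a printed carrier of 50.7 MHz with a volume coil capable of
#' roughly 2 G of B1.
#'
#' @param B0 Static field strength (tesla).
#' @param f0 Carrier frequency (MHz). Because f0 is in MHz, `f0` is also the
#'   Hz-per-ppm conversion factor.
#' @param gamma Gyromagnetic ratio of carbon-13 (Hz/gauss).
#' @param b1_max Maximum achievable RF amplitude (gauss).
#' @return An object of class `field_params`.
#' @export
#' @examples
#' fp <- field_params()
#' ppm_to_hz(12.3, fp)
field_params <- function(B0 = 4.7, f0 = 50.7, gamma = 1070.8, b1_max = 2.0) {
  stopifnot(B0 > 0, f0 > 0, gamma > 0, b1_max > 0)
  structure(list(B0 = B0, f0 = f0, gamma = gamma, b1_max = b1_max),
            class = "field_params")
}

#' @export
print.field_params <- function(x, ...) {
  cat(sprintf("<field_params> B0 = %.2f T, f0 = %.2f MHz, gamma = %.1f Hz/G, B1max = %.2f G\n",
              x$B0, x$f0, x$gamma, x$b1_max))
  invisible(x)
}

#' Carbon-13 metabolite table
#'
#' Chemical shifts and relaxation times for the species relevant to
#' hyperpolarized [1-13C]pyruvate experiments. Shifts are on the standard
#' carbon ppm scale; pyruvate (172.0), lactate (184.3), alanine (177.7) and
#' pyruvate hydrate (180.4) are spectroscopy standards. T2 values and the
#' urea reference shift are synthetic-model parameters (not measured
#' quantities) and can be overridden.
#'
#' @param t2_default Transverse relaxation default (s) applied where no value
#'   is given.
#' @param urea_shift_ppm Chemical shift assumed for the external urea
#'   reference vial (ppm).
#' @return A data.frame with columns `name`, `shift_ppm`, `t1`, `t2`.
#' @export
metabolite_table <- function(t2_default = 0.1, urea_shift_ppm = 163.5) {
  tb <- data.frame(
    name      = c("pyruvate", "lactate", "alanine", "pyruvate_hydrate", "urea"),
    shift_ppm = c(172.0, 184.3, 177.7, 180.4, urea_shift_ppm),
    t1        = c(65, 33, 40, 30, 20),
    t2        = rep(t2_default, 5),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(tb$shift_ppm), all(tb$t1 > 0), all(tb$t2 > 0),
            all(tb$t2 <= tb$t1))
  tb
}

met_row <- function(metab, name) {
  i <- match(name, metab$name)
  if (is.na(i)) stop("unknown metabolite: ", name, call. = FALSE)
  metab[i, ]
}

#' Convert a chemical-shift offset in ppm to Hz
#'
#' With the carrier frequency expressed in MHz, one ppm corresponds to
#' exactly `f0` Hz, so the conversion is `shift_ppm * f0`. Positive ppm means
#' higher frequency.
#'
#' @param shift_ppm Offset in ppm relative to the carrier.
#' @param field A [field_params()] object.
#' @return Frequency offset in Hz.
#' @export
ppm_to_hz <- function(shift_ppm, field = field_params()) {
  stopifnot(field$f0 > 0)
  shift_ppm * field$f0
}

#' Convert a frequency offset in Hz to ppm
#' @param hz Offset in Hz.
#' @param field A [field_params()] object.
#' @return Offset in ppm.
#' @export
hz_to_ppm <- function(hz, field = field_params()) hz / field$f0

#' 2D acquisition geometry
#'
#' @param matrix Integer pair: samples per in-plane dimension.
#' @param fov Numeric pair: field of view per dimension (mm).
#' @param slice_thickness Slice thickness (mm).
#' @return An object of class `geometry2d`.
#' @export
#' @examples
#' resolution(geometry2d(c(16, 16), c(80, 80), 20))  # 5 x 5 mm
geometry2d <- function(matrix = c(16L, 16L), fov = c(80, 80),
                       slice_thickness = 20) {
  matrix <- as.integer(matrix)
  if (length(matrix) == 1L) matrix <- rep(matrix, 2L)
  if (length(fov) == 1L) fov <- rep(fov, 2L)
  if (any(matrix < 1L)) stop("invalid geometry: matrix entries must be >= 1",
                             call. = FALSE)
  stopifnot(length(matrix) == 2L, length(fov) == 2L, all(fov > 0),
            slice_thickness > 0)
  structure(list(matrix = matrix, fov = fov, slice_thickness = slice_thickness),
            class = "geometry2d")
}

#' @export
print.geometry2d <- function(x, ...) {
  r <- resolution(x)
  cat(sprintf("<geometry2d> %d x %d, FOV %g x %g mm (%g x %g mm voxels), slice %g mm\n",
              x$matrix[1], x$matrix[2], x$fov[1], x$fov[2], r[1], r[2],
              x$slice_thickness))
  invisible(x)
}

#' In-plane voxel size of a 2D geometry
#'
#' @param geom A [geometry2d()] object.
#' @return Numeric pair: voxel size per dimension (mm), `fov / matrix`.
#' @export
resolution <- function(geom) {
  if (any(geom$matrix < 1L)) stop("invalid geometry: zero matrix entry",
                                  call. = FALSE)
  geom$fov / geom$matrix
}

#' Centered voxel-center coordinates along one image dimension
#'
#' 0-based index `i` maps to `(i - n/2) * dx`, so the DC voxel sits at
#' index `n %/% 2`.
#'
#' @param n Number of voxels.
#' @param fov_mm Field of view (mm).
#' @return Voxel-center positions in cm.
#' @export
grid_coords_cm <- function(n, fov_mm) {
  ((seq_len(n) - 1) - n %/% 2) * (fov_mm / n) / 10
}

#' Default run configuration
#'
#' Nested list of every tunable parameter of the virtual experiment: field
#' and metabolite constants, SSRF design specifications, acquisition
#' geometry, protocol schedule, phantom construction and kinetic parameters,
#' and noise levels. Values mirror the packaged YAML config
#' (`system.file("extdata", "default_config.yaml", package = "hpmri")`).
#'
#' @return A nested list.
#' @export
default_config <- function() {
  list(
    field = list(B0 = 4.7, f0 = 50.7, gamma = 1070.8, b1_max = 2.0),
    metabolites = list(t2_default = 0.1, urea_shift_ppm = 163.5),
    design = list(
      flip_pyruvate = 20, flip_lactate = 90,
      pass_halfwidth_ppm = 0.5, tbw_spectral = 3.5, max_ripple = 0.01,
      ripple_margin = 0.9, tbw_spatial = 4,
      slice_thickness = 20, grad_max = 10, slew_max = 200,
      dwell = 4, subpulse_flat_ms = 0.40, b1_peak_max = 0.4,
      n_taps_max = 24
    ),
    epi = list(matrix = c(16L, 16L), fov = c(80, 80), slice_thickness = 20,
               adc_dwell_us = 16),
    csi = list(matrix = c(8L, 8L), fov = c(80, 80), slice_thickness = 20,
               flip = 10, sw = 25000, np = 2048, tr_ms = 82),
    slab = list(flip = 5, sw = 10000, np = 2048, tr_ms = 1200,
                thickness_mm = 40),
    schedule = list(interval = 3, duration = 60, start_delay = 20,
                    flip_pyruvate = 20, flip_lactate = 90),
    phantom = list(matrix = c(64L, 64L), fov = c(80, 80), slice_thickness = 20,
                   b0_rms = 15, b0_max = 60, chest_offset_hz = 60,
                   kpl_tissue = 0.02, kpl_kidney = 0.05, kpl_chest = 0.03,
                   t1_lactate = 33, inflow_peak_t = 12, inflow_shape = 2.5,
                   urea_amp = 0.5, t2star_ms = 30),
    noise = list(epi_sigma = 0, csi_sigma = 0, slab_sigma = 0),
    calibration = list(search_halfwidth_hz = 300, min_snr = 5),
    recon = list(lb_hz = 12, window_halfwidth_ppm = 1.5),
    seed = 1L
  )
}

merge_config <- function(base, override, path = "") {
  for (k in names(override)) {
    here <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base))
      stop("unknown config key: ", here, call. = FALSE)
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(override[[k]]))
        stop("config key ", here, " must be a mapping", call. = FALSE)
      base[[k]] <- merge_config(base[[k]], override[[k]], here)
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Load a run configuration from YAML or JSON
#'
#' Unknown keys are rejected with the offending key path; values present in
#' the file override the defaults from [default_config()].
#'
#' @param path Path to a YAML (`.yaml`/`.yml`) or JSON file, or `NULL` for
#'   the defaults.
#' @return A validated config list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  merge_config(cfg, raw)
}

config_field <- function(cfg) {
  do.call(field_params, cfg$field)
}

config_metabolites <- function(cfg) {
  do.call(metabolite_table, cfg$metabolites)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
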