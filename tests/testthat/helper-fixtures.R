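# Shared fixtures. Pulse design is the expensive step (tens of seconds),
# so designs are memoized for the duration of the test run.
.design_cache <- new.env(parent = emptyenv())

cached_pulse <- function(name) {
  if (is.null(.design_cache[[name]]))
    assign(name, design_metabolite_pulse(name), envir = .design_cache)
  .design_cache[[name]]
}

# Band layout (Hz) used when checking a pulse against its specification:
# passband +/-0.5 ppm around its own resonance, stopbands of the same width
# at the other species of the pyruvate spin system.
pulse_bands_hz <- function(metabolite, field = field_params(),
                           metab = metabolite_table()) {
  own <- metab$shift_ppm[metab$name == metabolite]
  others <- setdiff(c("pyruvate", "lactate", "alanine", "pyruvate_hydrate"),
                    metabolite)
  hw <- ppm_to_hz(0.5, field)
  stop_list <- lapply(others, function(nm) {
    c0 <- ppm_to_hz(metab$shift_ppm[metab$name == nm] - own, field)
    c(c0 - hw, c0 + hw)
  })
  names(stop_list) <- others
  list(pass = c(-hw, hw), stop = stop_list)
}

# frequency grid covering all bands of a pulse densely
band_union_grid <- function(bands, n_per_band = 129L) {
  sort(unique(c(
    seq(bands$pass[1], bands$pass[2], length.out = n_per_band),
    unlist(lapply(bands$stop, function(b)
      seq(b[1], b[2], length.out = n_per_band))))))
}

# quiet flat-weight stand-in pulse for scanner tests that bypass excitation
# profiles (w supplied explicitly)
flat_pulse <- function(metabolite, flip = 20, center_offset_hz = 0) {
  structure(list(metabolite = metabolite, flip = flip,
                 center_offset_hz = center_offset_hz),
            class = "ssrf_pulse")
}

# small clean phantom (no B0 structure) for signal-model tests
clean_phantom <- function(n = 32L, seed = 11L) {
  ph <- build_rat_phantom(geometry2d(c(n, n), c(80, 80), 20), seed = seed,
                          b0_rms = 0, chest_offset_hz = 0)
  ph
}

# state with unit pyruvate in the whole body and frozen kinetics
static_state <- function(phantom, pyr = 1, lac = 0) {
  st <- hp_state(phantom)
  st$inflow_amp[] <- 0
  st$kpl[] <- 0
  st$t1[] <- Inf
  st$mz[phantom$body, "pyruvate"] <- pyr
  st$mz[phantom$body, "lactate"] <- lac
  st
}

# center of mass of the 3x3 neighborhood of the image maximum, in voxels
peak_com <- function(img) {
  m <- Mod(img)
  i <- which(m == max(m), arr.ind = TRUE)[1, ]
  ii <- ((i[1] + (-1:1) - 1) %% nrow(m)) + 1
  jj <- ((i[2] + (-1:1) - 1) %% ncol(m)) + 1
  w <- m[ii, jj]
  c(i[1] + sum((-1:1) * rowSums(w)) / sum(w),
    i[2] + sum((-1:1) * colSums(w)) / sum(w))
}

with_seed_test <- function(seed, code) withr::with_seed(seed, code)
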