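synthetic_spectrum <- function(freq_hz, amp = 1, sw = 10000, np = 2048,
                               t2star = 0.03, noise = 0, seed = 1) {
  tt <- (seq_len(np) - 1) / sw
  fid <- complex(np)
  for (i in seq_along(freq_hz))
    fid <- fid + amp[i] * exp(2i * pi * freq_hz[i] * tt) * exp(-tt / t2star)
  if (noise > 0)
    fid <- fid + with_seed_test(seed,
      complex(real = stats::rnorm(np), imaginary = stats::rnorm(np))) * noise
  structure(list(fids = array(fid, c(np, 1, 1)), sw = sw, np = np,
                 tr_ms = NA, flip = 5, geom = NULL, t_acq = 0,
                 noise_sigma = noise, carrier_hz = 0),
            class = "spectral_grid")
}

test_that("peak picking finds a Lorentzian to sub-bin accuracy", {
  sp <- synthetic_spectrum(137.0, noise = 0.02, seed = 5)
  pk <- find_pyruvate_peak(sp, c(-300, 300), min_snr = 5)
  expect_lt(abs(pk$freq - 137.0), 4.8828125)  # within one bin, usually far less
  expect_gt(pk$snr, 5)
  # pure noise raises a calibration failure
  sp0 <- synthetic_spectrum(numeric(0), sw = 10000, np = 2048,
                            noise = 0.5, seed = 7)
  expect_error(find_pyruvate_peak(sp0, c(-300, 300), min_snr = 5),
               "calibration failure")
  expect_error(find_pyruvate_peak(sp, c(-6000, 6000)), "search window")
})

test_that("the tallest in-window peak wins over urea and lactate", {
  # urea far below the window, pyruvate dominant, small lactate
  sp <- synthetic_spectrum(c(-430.9, 40, 663.6), amp = c(0.8, 2, 0.25),
                           noise = 0.01, seed = 3)
  pk <- find_pyruvate_peak(sp, c(-300, 300), min_snr = 5)
  expect_lt(abs(pk$freq - 40), 4.8828125)
})

test_that("offset computation follows the retuning rules exactly", {
  fp <- field_params(); met <- metabolite_table()
  cal <- compute_offsets(0, met, field = fp)
  expect_equal(cal$pulse_offsets[["lactate"]], 623.61)
  expect_equal(cal$pulse_offsets[["lactate"]] -
                 cal$pulse_offsets[["pyruvate"]],
               ppm_to_hz(184.3 - 172.0, fp))
  # passband centered on its metabolite -> zero reconstruction shift
  expect_equal(unname(cal$recon_shifts), c(0, 0))
  # degenerate table with (near-)coincident shifts -> offsets collapse to 0
  met2 <- met; met2$shift_ppm <- 172.0 + (seq_len(nrow(met2)) - 1) * 1e-9
  cal2 <- compute_offsets(0, met2, field = fp)
  expect_lt(max(abs(cal2$pulse_offsets)), 1e-6)
  expect_lt(max(abs(cal2$recon_shifts)), 1e-12)
})

test_that("injected global shifts are recovered to within one bin", {
  fp <- field_params(); met <- metabolite_table(t2_default = 10)
  bin <- 10000 / 2048
  for (shift in c(-300, -80, 0, 150, 300)) {
    ph <- build_rat_phantom(geometry2d(c(32, 32), c(80, 80), 20), seed = 9L,
                            b0_rms = 0, chest_offset_hz = 0)
    ph$b0_map[ph$body] <- shift
    st <- static_state(ph, pyr = 1, lac = 0.05)
    sl <- acquire_slab_spectrum(ph, st, field = fp, metab = met,
                                slab = list(axis = 2, range_mm = c(-40, 15)))
    pk <- find_pyruvate_peak(sl$spectrum, c(-330, 330))
    expect_lt(abs(pk$freq - shift), bin)
  }
})

test_that("calibration is idempotent on a static phantom", {
  fp <- field_params(); met <- metabolite_table(t2_default = 10)
  ph <- build_rat_phantom(geometry2d(c(32, 32), c(80, 80), 20), seed = 10L,
                          b0_rms = 0, chest_offset_hz = 0)
  ph$b0_map[ph$body] <- 120
  st <- static_state(ph, pyr = 1, lac = 0.05)
  sl1 <- acquire_slab_spectrum(ph, st, field = fp, metab = met)
  pk1 <- find_pyruvate_peak(sl1$spectrum)
  # retune and scan again: the residual offset is below one bin
  sl2 <- acquire_slab_spectrum(ph, sl1$state, field = fp, metab = met,
                               carrier_hz = pk1$freq)
  pk2 <- find_pyruvate_peak(sl2$spectrum)
  expect_lt(abs(pk2$freq), 10000 / 2048)
})

test_that("autocal restores EPI positions under a global B0 shift", {
  fp <- field_params(); met <- metabolite_table(t2_default = 10)
  tr <- make_flyback_trajectory(geometry2d(c(16, 16), c(80, 80), 20),
                                field = fp)
  pulses <- list(pyruvate = cached_pulse("pyruvate"),
                 lactate = cached_pulse("lactate"))
  sched <- protocol_schedule(3, 3, start_delay = 0)
  run_one <- function(shift) {
    ph <- build_rat_phantom(geometry2d(c(64, 64), c(80, 80), 20), seed = 4L,
                            b0_rms = 0, chest_offset_hz = 0)
    ph$b0_map[ph$body] <- shift
    st <- static_state(ph, pyr = 1, lac = 0.3)
    out <- run_autocal_then_epi(ph, st, sched, pulses, tr, seed = 1L,
                                field = fp, metab = met)
    ser <- recon_epi_series(out$frames, tr, out$cal$recon_shifts)
    list(cal = out$cal, pyr = ser$images$pyruvate[, , 1])
  }
  ref <- run_one(0)
  shifted <- run_one(80)
  expect_lt(abs(shifted$cal$pyruvate_freq - 80), 10000 / 2048)
  dcom <- peak_com(shifted$pyr) - peak_com(ref$pyr)
  expect_lt(sqrt(sum(dcom^2)), 0.1)
})

test_that("autocal failure prevents any EPI acquisition", {
  fp <- field_params(); met <- metabolite_table(t2_default = 10)
  ph <- build_rat_phantom(geometry2d(c(32, 32), c(80, 80), 20), seed = 12L,
                          b0_rms = 0, chest_offset_hz = 0)
  ph$urea_amp <- 0
  st <- static_state(ph, pyr = 0)   # nothing to detect
  tr <- make_flyback_trajectory(geometry2d(c(16, 16), c(80, 80), 20),
                                field = fp)
  pulses <- list(pyruvate = cached_pulse("pyruvate"),
                 lactate = cached_pulse("lactate"))
  expect_error(run_autocal_then_epi(ph, st, protocol_schedule(3, 3),
                                    pulses, tr, seed = 1L, field = fp,
                                    metab = met, slab_noise_sigma = 1e-5),
               "calibration failure")
})
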