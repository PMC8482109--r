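test_that("spectral filter design is deterministic and honest about ripple", {
  fp <- field_params()
  spec <- ssrf_design_spec(flip = 20,
                           stopbands_ppm = list(c(12.3, 0.5), c(5.7, 0.5),
                                                c(8.4, 0.5)))
  sub <- design_spatial_subpulse(spec, fp)
  f1 <- design_spectral_filter(spec, 10L, fp, sub)
  f2 <- design_spectral_filter(spec, 10L, fp, sub)
  expect_identical(f1$taps, f2$taps)
  # brute-force DTFT oracle (explicit double loop, no matrix shortcuts)
  # reproduces the designer's reported band ripple
  env <- hpmri:::subpulse_envelope(sub, spec$dwell)
  for (j in seq_len(nrow(f1$bands))) {
    b <- f1$bands[j, ]
    fg <- seq(b$center - b$halfwidth, b$center + b$halfwidth,
              length.out = 512L)
    resp <- vapply(fg, function(f) {
      acc <- 0 + 0i
      for (k in seq_along(f1$taps))
        acc <- acc + f1$taps[k] *
          exp(-2i * pi * f * (k - 1 - (length(f1$taps) - 1) / 2) * sub$tau_s)
      Mod(env(f) * acc - b$desired)
    }, numeric(1))
    expect_lt(abs(max(resp) - f1$ripple[j]), 1e-9)
  }
})

test_that("degenerate and infeasible specs are handled explicitly", {
  fp <- field_params()
  loose <- ssrf_design_spec(flip = 20, max_ripple = 0.999)
  sub <- design_spatial_subpulse(loose, fp)
  f1 <- design_spectral_filter(loose, 1L, fp, sub)
  expect_true(f1$converged)
  expect_length(f1$taps, 1L)
  expect_error(ssrf_design_spec(flip = 20,
                                stopbands_ppm = list(c(0.6, 0.5))),
               "infeasible design")
  tight <- ssrf_design_spec(flip = 20, max_ripple = 1e-4,
                            stopbands_ppm = list(c(2, 0.5)))
  sub2 <- design_spatial_subpulse(tight, fp)
  expect_error(design_spectral_filter(tight, 3L, fp, sub2),
               "infeasible design")
})

test_that("spatial sub-pulse follows the slice-select gradient relation", {
  fp <- field_params()
  s20 <- design_spatial_subpulse(ssrf_design_spec(slice_thickness = 20), fp)
  s40 <- design_spatial_subpulse(ssrf_design_spec(slice_thickness = 40), fp)
  # doubling the thickness halves the gradient (same flat time)
  expect_equal(s20$G, 2 * s40$G)
  t_flat <- s20$n_flat * 4e-6
  expect_equal(s20$G, 4 / (fp$gamma * t_flat * 2))
  # flyback rewinder refunds the full lobe area
  expect_equal(sum(s20$period_grad), 0, tolerance = 1e-12)
})

test_that("designed pulses respect hardware limits sample-by-sample", {
  fp <- field_params()
  for (nm in c("pyruvate", "lactate")) {
    p <- cached_pulse(nm)
    expect_true(check_pulse_hardware(p, fp))
    expect_equal(length(p$rf), length(p$grad))
    expect_equal(p$duration, length(p$rf) * p$dwell / 1000)
    expect_lte(p$b1_peak, p$spec$b1_peak_max)
    # RF only during gradient flat-tops (flyback convention)
    on_flat <- abs(p$grad - p$subpulse$G) < 1e-9
    expect_true(all(Mod(p$rf)[!on_flat] < 1e-12))
  }
})

test_that("all-zero filter assembles to zero RF on an unchanged train", {
  fp <- field_params()
  spec <- ssrf_design_spec(flip = 20)
  sub <- design_spatial_subpulse(spec, fp)
  filt <- design_spectral_filter(spec, 6L, fp, sub,
                                 ripples = list(pass = 0.99, stop = 0.99),
                                 must_converge = FALSE)
  filt$taps <- filt$taps * 0
  filt$A0 <- 1 + 0i  # keep the amplitude map finite; zero taps -> zero RF
  p <- assemble_ssrf(filt, sub, spec, fp)
  expect_true(all(Mod(p$rf) == 0))
  expect_equal(p$grad, c(rep(sub$period_grad, 6),
                         p$grad[(6 * length(sub$period_grad) + 1):
                                  length(p$grad)]))
})

test_that("spectral response replicates at the sub-pulse repetition rate", {
  fp <- field_params()
  p <- cached_pulse("pyruvate")
  rep_hz <- 1 / p$subpulse$tau_s
  prof <- simulate_profile(p, 0, c(0, rep_hz), fp)
  frac <- Mod(prof$mxy[1, ]) / sin(20 * pi / 180)
  # replica passband at one replication period (sub-pulse envelope shrinks
  # it, but it is unmistakably a passband, not a stopband)
  expect_gt(frac[2], 0.5 * frac[1])
})

test_that("flip scaling is exact at the calibration point", {
  fp <- field_params()
  pyr <- cached_pulse("pyruvate")
  lac <- cached_pulse("lactate")
  expect_equal(measure_flip(simulate_profile(pyr, 0, 0, fp), 0, 0), 20,
               tolerance = 0.5 / 20)
  expect_equal(measure_flip(simulate_profile(lac, 0, 0, fp), 0, 0), 90,
               tolerance = 0.5 / 90)
  z <- scale_to_flip(pyr, 0, fp)
  expect_true(all(Mod(z$rf) == 0))
  # small-tip: analytic amplitude ratio agrees with the iterative result
  p5 <- scale_to_flip(pyr, 5, fp)
  expect_equal(max(Mod(p5$rf)) / max(Mod(pyr$rf)), 5 / 20, tolerance = 0.01)
})

test_that("designs land in the published duration and peak-B1 class", {
  pyr <- cached_pulse("pyruvate")
  lac <- cached_pulse("lactate")
  expect_gte(pyr$duration, 5); expect_lte(pyr$duration, 8)
  expect_gte(lac$duration, 10); expect_lte(lac$duration, 17)
  expect_gte(pyr$b1_peak, 0.1); expect_lte(pyr$b1_peak, 0.3)
  expect_gte(lac$b1_peak, 0.15); expect_lte(lac$b1_peak, 0.45)
})

test_that("slice profile width matches the prescribed thickness", {
  fp <- field_params()
  z <- seq(-3, 3, length.out = 241)
  for (nm in c("pyruvate", "lactate")) {
    prof <- simulate_profile(cached_pulse(nm), z, 0, fp)
    mag <- Mod(prof$mxy[, 1])
    fwhm <- diff(range(z[mag >= max(mag) / 2]))
    expect_gte(fwhm, 1.9)
    expect_lte(fwhm, 2.4)
  }
})

test_that("waveform center shifting is a pure phase modulation", {
  p <- cached_pulse("pyruvate")
  p2 <- shift_pulse_center(p, 623.61)
  expect_equal(Mod(p2$rf), Mod(p$rf))
  expect_equal(p2$center_offset_hz, 623.61)
  p3 <- shift_pulse_center(p2, 0)
  expect_equal(p3$rf, p$rf)
})
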