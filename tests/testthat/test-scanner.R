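test_that("flyback trajectory covers a complete Cartesian grid", {
  fp <- field_params()
  tr <- make_flyback_trajectory(geometry2d(c(16, 16), c(80, 80), 20),
                                field = fp)
  expect_length(tr$kx, 16)
  expect_equal(diff(tr$kx), rep(0.125, 15))
  expect_equal(tr$bw_phase * tr$esp_ms / 1000, 1, tolerance = 1e-12)
  expect_equal(tr$bw_read, 1 / 16e-6)
  # sample times increase along the readout and line by line
  expect_true(all(diff(as.vector(tr$t_ms)) > 0))
  tr1 <- make_flyback_trajectory(geometry2d(c(1, 1), c(80, 80), 20),
                                 field = fp)
  expect_equal(tr1$kx, 0)
  expect_equal(tr1$ky, 0)
  expect_error(make_flyback_trajectory(geometry2d(c(16, 16), c(8, 8), 20),
                                       field = fp),
               "infeasible trajectory")
})

test_that("noiseless on-resonance acquisition inverts through the recon", {
  fp <- field_params(); met <- metabolite_table(t2_default = 10)
  ph <- clean_phantom(64L)
  tr <- make_flyback_trajectory(geometry2d(c(16, 16), c(80, 80), 20),
                                field = fp)
  # point source at FOV center -> flat-magnitude k-space
  st <- static_state(ph, pyr = 0)
  st$mz[32 * 64 + 33, "pyruvate"] <- 1
  acq <- acquire_epi_frame(ph, st, flat_pulse("pyruvate"), tr, fp, met, w = 1)
  expect_lt(stats::sd(Mod(acq$frame$samples)) /
              mean(Mod(acq$frame$samples)), 1e-3)
  # disc phantom round-trip at acquisition resolution: only the T2 decay
  # over the readout perturbs the exact Fourier inversion (< 5% RMS)
  ph16 <- clean_phantom(16L)
  xs <- grid_coords_cm(16, 80); ys <- grid_coords_cm(16, 80)
  disc <- outer(xs, ys, function(x, y) x^2 + y^2 <= 2^2) * 1
  std <- static_state(ph16, pyr = 0)
  std$mz[, "pyruvate"] <- as.vector(disc)
  acq2 <- acquire_epi_frame(ph16, std, flat_pulse("pyruvate"), tr, fp, met,
                            w = 1)
  img <- Mod(recon_epi_frame(acq2$frame))
  img <- img / max(img)
  expect_lt(sqrt(mean((img - disc / max(disc))^2)), 0.05)
})

test_that("off-resonance displaces the image by the bandwidth fractions", {
  fp <- field_params(); met <- metabolite_table(t2_default = 10)
  ph <- clean_phantom(64L)
  tr <- make_flyback_trajectory(geometry2d(c(16, 16), c(80, 80), 20),
                                field = fp)
  # lactate source viewed by a pulse centered on pyruvate: df = +623.61 Hz
  st <- static_state(ph, pyr = 0)
  st$mz[32 * 64 + 33, "lactate"] <- 1
  acq <- acquire_epi_frame(ph, st, flat_pulse("lactate"), tr, fp, met, w = 1)
  st2 <- static_state(ph, pyr = 0)
  st2$mz[32 * 64 + 33, "pyruvate"] <- 1
  ref <- acquire_epi_frame(ph, st2, flat_pulse("pyruvate"), tr, fp, met,
                           w = 1)
  # the off-resonance phase accrual is a linear phase ramp across k-space;
  # its slopes are the subvoxel displacements in voxels
  R <- acq$frame$samples / ref$frame$samples
  slope_read <- mean(Arg(R[2:16, ] / R[1:15, ]))
  slope_phase <- mean(Arg(R[, 2:16] / R[, 1:15]))
  shift_read <- 623.61 / tr$bw_read * 16
  shift_phase <- 623.61 / tr$bw_phase * 16
  expect_equal(abs(slope_read) * 16 / (2 * pi), shift_read,
               tolerance = 1e-3)
  wrap_vox <- function(v) min(v %% 16, 16 - v %% 16)
  expect_equal(abs(slope_phase) * 16 / (2 * pi), wrap_vox(shift_phase),
               tolerance = 1e-3)
})

test_that("dynamic EPI bookkeeping matches the published schedule", {
  fp <- field_params(); met <- metabolite_table(t2_default = 10)
  ph <- clean_phantom(24L)
  tr <- make_flyback_trajectory(geometry2d(c(8, 8), c(80, 80), 20),
                                field = fp)
  sched <- protocol_schedule(3, 60)
  expect_equal(sched$n_frames, 20)
  expect_equal(protocol_schedule(3, 0)$n_frames, 0)
  st <- static_state(ph)
  pulses <- list(pyruvate = cached_pulse("pyruvate"),
                 lactate = cached_pulse("lactate"))
  short <- protocol_schedule(3, 9, start_delay = 0)
  run <- run_dynamic_epi(ph, st, short, pulses, tr, fp, met)
  expect_length(run$frames, 6)
  expect_equal(vapply(run$frames, function(f) f$metabolite, character(1)),
               rep(c("pyruvate", "lactate"), 3))
  tacq <- vapply(run$frames, function(f) f$t_acq, numeric(1))
  expect_true(all(diff(tacq) >= 0))
  # empty schedule -> empty series
  run0 <- run_dynamic_epi(ph, st, protocol_schedule(3, 0), pulses, tr,
                          fp, met)
  expect_length(run0$frames, 0)
})

test_that("magnetization ledger matches the closed-form consumption", {
  fp <- field_params(); met <- metabolite_table(t2_default = 10)
  ph <- clean_phantom(24L)
  tr <- make_flyback_trajectory(geometry2d(c(8, 8), c(80, 80), 20),
                                field = fp)
  # RF-only (frozen relaxation): after k pyruvate frames at 20 degrees with
  # unit weight, mz = cos(20 deg)^k
  st <- static_state(ph)
  for (k in 1:20)
    st <- acquire_epi_frame(ph, st, flat_pulse("pyruvate", 20), tr, fp,
                            met, w = 1)$state
  i <- which(ph$body)
  expect_equal(st$mz[i, "pyruvate"], rep(cos(20 * pi / 180)^20, length(i)),
               tolerance = 1e-6)
})

test_that("CSI consumes one hard pulse per phase encode", {
  fp <- field_params(); met <- metabolite_table(t2_default = 10)
  ph <- clean_phantom(24L)
  st <- static_state(ph)
  acq <- acquire_csi_frame(ph, st, geometry2d(c(8, 8), c(80, 80), 20),
                           flip = 10, sw = 25000, np = 256, tr_ms = 82,
                           field = fp, metab = met)
  expect_equal(dim(acq$grid$fids), c(256, 8, 8))
  # 64 excitations in one frame; frame period = 64 * TR
  expect_equal(acq$state$t - st$t, 64 * 0.082, tolerance = 1e-9)
  i <- which(ph$body)
  expect_equal(unname(acq$state$mz[i[1], "pyruvate"]), cos(10 * pi / 180)^64,
               tolerance = 1e-9)
  # six frames leave cos(10 deg)^384 ~ 0.0028 from RF alone
  st6 <- st
  for (k in 1:6)
    st6 <- acquire_csi_frame(ph, st6, geometry2d(c(8, 8), c(80, 80), 20),
                             flip = 10, sw = 25000, np = 64, tr_ms = 82,
                             field = fp, metab = met)$state
  expect_equal(unname(st6$mz[i[1], "pyruvate"]), cos(10 * pi / 180)^384,
               tolerance = 1e-6)
})

test_that("slab spectrum respects the slab and feeds calibration", {
  fp <- field_params(); met <- metabolite_table(t2_default = 10)
  ph <- build_rat_phantom(geometry2d(c(64, 64), c(80, 80), 20), seed = 2L,
                          b0_rms = 0, chest_offset_hz = 0)
  st <- static_state(ph, pyr = 1, lac = 0.05)
  # default slab excludes the chest: zero chest contribution to the FID
  sl <- acquire_slab_spectrum(ph, st, field = fp, metab = met)
  chest <- which(ph$masks$chest)
  expect_equal(sl$state$mz[chest, "pyruvate"], rep(1, length(chest)))
  # spectral bin width of the slab protocol
  expect_equal(sl$spectrum$sw / sl$spectrum$np, 4.8828125)
  # pyruvate is the tallest tissue peak early after injection
  pk <- find_pyruvate_peak(sl$spectrum)
  expect_lt(abs(pk$freq), 4.8828125)
  expect_error(acquire_slab_spectrum(ph, st,
                                     slab = list(axis = 2,
                                                 range_mm = c(39, 40)),
                                     field = fp, metab = met),
               "empty slab")
})

test_that("acquisition noise magnitude is Rayleigh distributed", {
  fp <- field_params(); met <- metabolite_table(t2_default = 10)
  ph <- clean_phantom(24L)
  tr <- make_flyback_trajectory(geometry2d(c(64, 64), c(80, 80), 20),
                                field = fp)
  st <- static_state(ph, pyr = 0)   # empty object: pure noise
  sigma <- 0.7
  acq <- acquire_epi_frame(ph, st, flat_pulse("pyruvate"), tr, fp, met,
                           noise_sigma = sigma, seed = 31L, w = 1)
  mags <- Mod(as.vector(acq$frame$samples))
  ks <- stats::ks.test(mags, function(q) 1 - exp(-q^2 / (2 * sigma^2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("swept-frequency profile measurement mirrors the simulation", {
  fp <- field_params()
  # zero pulse sweeps to a zero profile
  zp <- scale_to_flip(cached_pulse("pyruvate"), 0, fp)
  m0 <- measure_pulse_profile(zp, c(-200, 200), 5L, field = fp)
  expect_true(all(Mod(m0$mxy) == 0))
  p <- cached_pulse("pyruvate")
  meas <- measure_pulse_profile(p, c(-650, 650), 53L, field = fp)
  zg <- seq(-2.5, 2.5, length.out = 41)
  fg <- seq(-600, 600, length.out = 49)
  sim <- simulate_profile(p, zg, fg, fp)
  meas_r <- regrid_profile(meas, zg, fg)
  rms <- sqrt(mean((Mod(sim$mxy) - Mod(meas_r$mxy))^2))
  expect_lt(rms / max(Mod(sim$mxy)), 0.05)
  # the lactate offset column stays under 1% of the passband amplitude
  col <- meas$z >= -1 & meas$z <= 1
  j <- which.min(abs(meas$f - 623.61))
  jc <- which.min(abs(meas$f))
  expect_lt(max(Mod(meas$mxy[col, j])), 0.01 * max(Mod(meas$mxy[col, jc])))
})
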