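test_that("EPI reconstruction is the exact inverse transform", {
  # flat k-space -> point source at the center voxel
  flat <- matrix(1 + 0i, 16, 16)
  img <- recon_epi_frame(flat)
  pk <- which(Mod(img) == max(Mod(img)), arr.ind = TRUE)
  expect_equal(as.vector(pk), c(9, 9))
  expect_equal(Mod(img[9, 9]), 1)
  # forward-then-inverse identity on a random grid
  set.seed(4)
  r <- matrix(complex(real = stats::rnorm(256),
                      imaginary = stats::rnorm(256)), 16, 16)
  back <- recon_epi_frame(hpmri:::forward_epi_frame(r))
  expect_lt(max(Mod(back - r)) / max(Mod(r)), 1e-12)
  bad <- flat; bad[3, 4] <- NA
  expect_error(recon_epi_frame(bad), "incomplete")
})

test_that("chemical-shift correction is an invertible subvoxel shift", {
  fp <- field_params()
  tr <- make_flyback_trajectory(geometry2d(c(16, 16), c(80, 80), 20),
                                field = fp)
  set.seed(8)
  img <- matrix(complex(real = stats::rnorm(256),
                        imaginary = stats::rnorm(256)), 16, 16)
  expect_identical(apply_chemshift_shift(img, 0, tr), img)
  fwd <- apply_chemshift_shift(img, 150, tr)
  back <- apply_chemshift_shift(fwd, -150, tr)
  expect_lt(max(Mod(back - img)), 1e-10)
})

test_that("acquire-then-correct restores an off-resonance source", {
  fp <- field_params(); met <- metabolite_table(t2_default = 10)
  ph <- clean_phantom(64L)
  tr <- make_flyback_trajectory(geometry2d(c(16, 16), c(80, 80), 20),
                                field = fp)
  df <- 623.61
  st <- static_state(ph, pyr = 0)
  st$mz[32 * 64 + 33, "lactate"] <- 1
  acq <- acquire_epi_frame(ph, st, flat_pulse("lactate"), tr, fp, met, w = 1)
  corrected <- apply_chemshift_shift(recon_epi_frame(acq$frame), df, tr)
  # ground truth: the same source acquired on resonance
  st2 <- static_state(ph, pyr = 0)
  st2$mz[32 * 64 + 33, "pyruvate"] <- 1
  ref <- recon_epi_frame(acquire_epi_frame(ph, st2, flat_pulse("pyruvate"),
                                           tr, fp, met, w = 1)$frame)
  dcom <- peak_com(corrected) - peak_com(ref)
  expect_lt(sqrt(sum(dcom^2)), 0.1)
})

test_that("exponential apodization follows the line-broadening convention", {
  fid <- complex(real = stats::rnorm(128), imaginary = stats::rnorm(128))
  expect_identical(apodize_fid(fid, 0, 1e-3), fid)
  ap <- apodize_fid(fid, 12, 1e-3)
  expect_identical(ap[1], fid[1])   # t = 0 sample untouched
  expect_error(apodize_fid(fid, -1, 1e-3), "negative")
  # a 2 Hz Lorentzian apodized at 12 Hz shows a 14 Hz FWHM
  sw <- 2000; np <- 4096
  tt <- (seq_len(np) - 1) / sw
  fid_l <- exp(-pi * 2 * tt) + 0i
  # absorption-mode line (real part); the magnitude line is sqrt(3) wider
  spec <- Re(hpmri:::fid_spectrum(apodize_fid(fid_l, 12, 1 / sw)))
  fax <- hpmri:::spectral_axis(np, sw)
  half <- max(spec) / 2
  fwhm <- diff(range(fax[spec >= half]))
  expect_equal(fwhm, 14, tolerance = (sw / np) * 2 / 14)
})

test_that("CSI maps localize species and respond linearly", {
  fp <- field_params(); met <- metabolite_table(t2_default = 10)
  ph <- clean_phantom(32L)
  g8 <- geometry2d(c(8, 8), c(80, 80), 20)
  # single-voxel lactate: lactate map peaks there, pyruvate map at noise
  st <- static_state(ph, pyr = 0)
  st$mz[, "lactate"] <- 0
  st$mz[15 * 32 + 17, "lactate"] <- 1
  ph0 <- ph; ph0$urea_amp <- 0
  acq <- acquire_csi_frame(ph0, st, g8, flip = 10, sw = 25000, np = 512,
                           tr_ms = 82, field = fp, metab = met)
  ser <- recon_csi(acq$grid, lb = 12, metab = met, field = fp,
                   normalize = "none")
  lac <- ser$images$lactate[, , 1]
  pyr <- ser$images$pyruvate[, , 1]
  pk <- which(lac == max(lac), arr.ind = TRUE)
  expect_equal(as.vector(pk), c(5, 5))
  # far tail of the magnitude-mode lactate line is all that can leak
  expect_lt(max(pyr), 0.03 * max(lac))
  # zero input -> all-zero maps
  st0 <- static_state(ph0, pyr = 0)
  acq0 <- acquire_csi_frame(ph0, st0, g8, flip = 10, sw = 25000, np = 512,
                            tr_ms = 82, field = fp, metab = met)
  ser0 <- recon_csi(acq0$grid, lb = 12, metab = met, field = fp,
                    normalize = "none")
  expect_equal(max(ser0$images$pyruvate), 0)
  # two equal-amplitude voxels give equal map values
  st2 <- static_state(ph0, pyr = 0)
  st2$mz[7 * 32 + 9, "pyruvate"] <- 1
  st2$mz[23 * 32 + 25, "pyruvate"] <- 1
  acq2 <- acquire_csi_frame(ph0, st2, g8, flip = 10, sw = 25000, np = 512,
                            tr_ms = 82, field = fp, metab = met)
  m2 <- recon_csi(acq2$grid, lb = 12, metab = met, field = fp,
                  normalize = "none")$images$pyruvate
  v <- sort(as.vector(m2), decreasing = TRUE)[1:2]
  expect_lt(abs(v[1] - v[2]) / v[1], 0.01)
  expect_error(recon_csi(acq2$grid, metab = met, field = fp,
                         windows = list(a = c(-10, 10), b = c(5, 30))),
               "overlapping")
})

test_that("map amplitude is linear in source amplitude", {
  fp <- field_params(); met <- metabolite_table(t2_default = 10)
  ph <- clean_phantom(32L); ph$urea_amp <- 0
  g8 <- geometry2d(c(8, 8), c(80, 80), 20)
  vals <- vapply(c(1, 3), function(a) {
    st <- static_state(ph, pyr = 0)
    st$mz[15 * 32 + 17, "pyruvate"] <- a
    acq <- acquire_csi_frame(ph, st, g8, flip = 10, sw = 25000, np = 512,
                             tr_ms = 82, field = fp, metab = met)
    max(recon_csi(acq$grid, lb = 12, metab = met, field = fp,
                  normalize = "none")$images$pyruvate)
  }, numeric(1))
  expect_equal(vals[2] / vals[1], 3, tolerance = 1e-9)
})

test_that("ROI curves aggregate exactly and recover decay rates", {
  geom <- geometry2d(c(16, 16), c(80, 80), 20)
  nt <- 12
  rate <- 0.08
  arr <- array(rep(exp(-rate * (0:(nt - 1)) * 3), each = 256), c(16, 16, nt))
  ser <- structure(list(images = list(pyruvate = arr),
                        timestamps = (0:(nt - 1)) * 3, geometry = geom,
                        units = "snr"), class = "metab_image_series")
  m_all <- matrix(TRUE, 16, 16)
  cur <- extract_roi_curves(ser, list(all = m_all))
  expect_equal(cur$value, exp(-rate * cur$t))
  # disjoint masks partition the mean exactly
  m1 <- matrix(FALSE, 16, 16); m1[1:8, ] <- TRUE
  m2 <- !m1
  c2 <- extract_roi_curves(ser, list(a = m1, b = m2))
  va <- c2$value[c2$roi == "a"]; vb <- c2$value[c2$roi == "b"]
  expect_equal((va * sum(m1) + vb * sum(m2)) / 256, cur$value,
               tolerance = 1e-12)
  # monoexponential fit on the ROI curve recovers the generating rate
  fitr <- stats::lm(log(cur$value) ~ cur$t)
  expect_equal(-unname(coef(fitr)[2]), rate, tolerance = 0.05 * rate)
  expect_error(extract_roi_curves(ser, list(none = matrix(FALSE, 16, 16))),
               "empty mask")
})

test_that("SNR normalization calibrates pure noise to the Rayleigh mean", {
  fp <- field_params(); met <- metabolite_table(t2_default = 10)
  ph <- clean_phantom(24L)
  tr <- make_flyback_trajectory(geometry2d(c(64, 64), c(80, 80), 20),
                                field = fp)
  st <- static_state(ph, pyr = 0)
  frames <- lapply(1:2, function(k)
    acquire_epi_frame(ph, st, flat_pulse("pyruvate"), tr, fp, met,
                      noise_sigma = 0.4, seed = 100L + k, w = 1)$frame)
  ser <- recon_epi_series(frames, tr)
  roi <- extract_roi_curves(ser, list(all = matrix(TRUE, 64, 64)))
  expect_true(all(roi$value > 0.9 & roi$value < 1.5))
})
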