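#' Heatmap of a spectral-spatial magnetization profile
#'
#' @param x A `mag_profile`.
#' @param main Title.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly `x`.
#' @export
plot.mag_profile <- function(x, main = "|Mxy|", ...) {
  graphics::image(x$f, x$z, t(Mod(x$mxy)), xlab = "frequency offset (Hz)",
                  ylab = "position (cm)", main = main,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Temporally summed maps of a metabolite image series
#'
#' @param x A `metab_image_series`.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly `x`.
#' @export
plot.metab_image_series <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, length(x$images)), mar = c(2, 2, 3, 1))
  on.exit(graphics::par(op))
  for (nm in names(x$images)) {
    summed <- apply(x$images[[nm]], c(1, 2), sum)
    graphics::image(summed, axes = FALSE, main = paste(nm, "(summed)"),
                    col = grDevices::hcl.colors(64, "inferno"), ...)
  }
  invisible(x)
}

png_to <- function(path, expr, width = 900, height = 450) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  force(expr)
  invisible(path)
}

#' Run the complete virtual experiment
#'
#' Orchestrates the full pipeline from one configuration: SSRF pulse design
#' for pyruvate and lactate, simulated (and optionally swept-measurement)
#' profile QC, phantom construction, automated center-frequency calibration
#' followed by dynamic EPI, dynamic CSI from an identical second injection,
#' reconstruction of both acquisitions, ROI time curves, and an HTML/PNG
#' report. All stages derive their randomness from `config$seed`.
#'
#' With `config$schedule$duration == 0` only the design and profile-QC
#' stages produce output (no dynamic frames).
#'
#' @param config A configuration list (see [default_config()],
#'   [load_config()]).
#' @param out_dir Output directory for the bundle.
#' @param pulses Optional pre-designed pulses (named list) to skip the
#'   design stage.
#' @param measure_profiles Also run the (slower) swept-frequency profile
#'   measurement emulation for the QC panels.
#' @param csi_frames Number of dynamic CSI frames.
#' @param verbose Emit progress messages.
#' @return Invisibly, a list with the main in-memory results (pulses,
#'   phantom, calibration, image series, curves) and `out_dir`.
#' @export
run_full_experiment <- function(config = default_config(), out_dir,
                                pulses = NULL, measure_profiles = FALSE,
                                csi_frames = 6L, verbose = TRUE) {
  config <- merge_config(default_config(), config)
  say <- function(...) if (verbose) message(...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  field <- config_field(config)
  metab <- config_metabolites(config)
  dz <- config$design
  spec0 <- ssrf_design_spec(
    flip = dz$flip_pyruvate, pass_halfwidth_ppm = dz$pass_halfwidth_ppm,
    tbw_spectral = dz$tbw_spectral, max_ripple = dz$max_ripple,
    slice_thickness = dz$slice_thickness, tbw_spatial = dz$tbw_spatial,
    grad_max = dz$grad_max, slew_max = dz$slew_max, dwell = dz$dwell,
    subpulse_flat_ms = dz$subpulse_flat_ms,
    ripple_margin = dz$ripple_margin, b1_peak_max = dz$b1_peak_max,
    n_taps_max = dz$n_taps_max)
  if (is.null(pulses)) {
    say("designing SSRF pulses ...")
    pulses <- list(
      pyruvate = design_metabolite_pulse("pyruvate", dz$flip_pyruvate,
                                         field, metab, spec0),
      lactate = design_metabolite_pulse("lactate", dz$flip_lactate,
                                        field, metab, spec0))
  }
  wf_dir <- file.path(out_dir, "waveforms")
  for (nm in names(pulses)) write_pulse_waveform(pulses[[nm]], wf_dir, nm)
  say("profile QC ...")
  zg <- seq(-3, 3, length.out = 61)
  fg <- seq(-600, 600, length.out = 121)
  qc_dir <- file.path(out_dir, "profiles")
  dir.create(qc_dir, showWarnings = FALSE)
  profiles <- list()
  for (nm in names(pulses)) {
    sim <- simulate_profile(pulses[[nm]], zg, fg, field)
    write_profile_json(sim, file.path(qc_dir, paste0(nm, "_simulated.json")))
    profiles[[nm]] <- list(simulated = sim)
    if (measure_profiles) {
      meas <- measure_pulse_profile(pulses[[nm]], c(-600, 600), 61L,
                                    field = field)
      meas_r <- regrid_profile(meas, zg, fg)
      write_profile_json(meas_r,
                         file.path(qc_dir, paste0(nm, "_measured.json")))
      profiles[[nm]]$measured <- meas_r
    }
    png_to(file.path(qc_dir, paste0(nm, "_profile.png")), {
      if (measure_profiles) {
        op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
        plot(profiles[[nm]]$simulated, main = paste(nm, "simulated"))
        plot(profiles[[nm]]$measured, main = paste(nm, "measured"))
      } else plot(profiles[[nm]]$simulated, main = paste(nm, "simulated"))
    })
  }
  say("building phantom ...")
  phz <- config$phantom
  ph_grid <- geometry2d(phz$matrix, phz$fov, phz$slice_thickness)
  phantom <- build_rat_phantom(ph_grid, seed = config$seed,
                               b0_rms = phz$b0_rms, b0_max = phz$b0_max,
                               chest_offset_hz = phz$chest_offset_hz,
                               params = phz)
  write_phantom_json(phantom, file.path(out_dir, "phantom.json"))
  sched <- protocol_schedule(config$schedule$interval,
                             config$schedule$duration,
                             c(pyruvate = config$schedule$flip_pyruvate,
                               lactate = config$schedule$flip_lactate),
                             config$schedule$start_delay)
  result <- list(pulses = pulses, phantom = phantom, profiles = profiles,
                 out_dir = out_dir)
  if (sched$n_frames > 0) {
    say("autocal + dynamic EPI ...")
    traj <- make_flyback_trajectory(
      geometry2d(config$epi$matrix, config$epi$fov,
                 config$epi$slice_thickness),
      dz$grad_max, dz$slew_max, config$epi$adc_dwell_us, field)
    state <- hp_state(phantom, metab)
    auto <- run_autocal_then_epi(
      phantom, state, sched, pulses, traj, seed = config$seed,
      field = field, metab = metab,
      search_halfwidth_hz = config$calibration$search_halfwidth_hz,
      min_snr = config$calibration$min_snr,
      noise_sigma = config$noise$epi_sigma,
      slab_noise_sigma = config$noise$slab_sigma)
    epi_series <- recon_epi_series(auto$frames, traj, auto$cal$recon_shifts)
    write_image_series_nifti(epi_series, file.path(out_dir, "epi"), "epi")
    say("dynamic CSI (second injection) ...")
    csi_geom <- geometry2d(config$csi$matrix, config$csi$fov,
                           config$csi$slice_thickness)
    cstate <- hp_state(phantom, metab)
    cstate <- evolve_hp_state(cstate, sched$start_delay)
    csi_grids <- vector("list", csi_frames)
    for (i in seq_len(csi_frames)) {
      acq <- acquire_csi_frame(phantom, cstate, csi_geom,
                               flip = config$csi$flip, sw = config$csi$sw,
                               np = config$csi$np, tr_ms = config$csi$tr_ms,
                               field = field, metab = metab,
                               noise_sigma = config$noise$csi_sigma,
                               seed = config$seed + 977L * i,
                               carrier_hz = auto$cal$carrier_hz)
      csi_grids[[i]] <- acq$grid
      cstate <- acq$state
    }
    csi_series <- recon_csi(csi_grids, lb = config$recon$lb_hz, metab = metab,
                            window_halfwidth_ppm =
                              config$recon$window_halfwidth_ppm,
                            field = field)
    write_image_series_nifti(csi_series, file.path(out_dir, "csi"), "csi")
    say("ROI curves ...")
    rois <- list(liver = phantom$masks$liver,
                 kidney = phantom$masks$kidney_L | phantom$masks$kidney_R)
    curves <- rbind(
      cbind(sequence = "epi",
            extract_roi_curves(epi_series,
                               lapply(rois, downsample_mask,
                                      geom_to = epi_series$geometry))),
      cbind(sequence = "csi",
            extract_roi_curves(csi_series,
                               lapply(rois, downsample_mask,
                                      geom_to = csi_series$geometry))))
    utils::write.csv(curves, file.path(out_dir, "roi_curves.csv"),
                     row.names = FALSE)
    png_to(file.path(out_dir, "summed_maps.png"), {
      op <- graphics::par(mfrow = c(2, 2), mar = c(1, 1, 3, 1))
      on.exit(graphics::par(op))
      for (sx in list(list(epi_series, "EPI"), list(csi_series, "CSI")))
        for (nm in names(sx[[1]]$images))
          graphics::image(apply(sx[[1]]$images[[nm]], c(1, 2), sum),
                          axes = FALSE, main = paste(sx[[2]], nm),
                          col = grDevices::hcl.colors(64, "inferno"))
    }, width = 800, height = 800)
    png_to(file.path(out_dir, "roi_curves.png"), {
      op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
      for (sq in c("epi", "csi")) {
        cc <- curves[curves$sequence == sq, ]
        graphics::matplot(
          x = matrix(cc$t, ncol = 4),
          y = matrix(cc$value, ncol = 4), type = "l", lty = 1,
          xlab = "time (s)", ylab = "SNR", main = toupper(sq))
        graphics::legend("topright", cex = 0.7, lty = 1, col = 1:4,
                         legend = unique(paste(cc$roi, cc$metabolite)))
      }
    })
    result <- c(result, list(cal = auto$cal, epi_series = epi_series,
                             csi_series = csi_series, curves = curves))
  }
  lines <- c("<html><body><h1>Metabolite-specific EPI virtual experiment</h1>",
             sprintf("<p>seed %d</p>", config$seed),
             unlist(lapply(names(pulses), function(nm)
               sprintf('<h2>%s pulse</h2><img src="profiles/%s_profile.png">',
                       nm, nm))),
             if (sched$n_frames > 0)
               c('<h2>Summed maps</h2><img src="summed_maps.png">',
                 '<h2>ROI curves</h2><img src="roi_curves.png">'),
             "</body></html>")
  writeLines(lines, file.path(out_dir, "index.html"))
  say("done: ", out_dir)
  invisible(result)
}
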