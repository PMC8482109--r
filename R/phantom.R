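## Evaluate code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

ellipse_mask <- function(xs, ys, cx, cy, ax, ay, angle = 0) {
  X <- outer(xs - cx, rep(1, length(ys)))
  Y <- outer(rep(1, length(xs)), ys - cy)
  ca <- cos(angle); sa <- sin(angle)
  U <- X * ca + Y * sa
  V <- -X * sa + Y * ca
  (U / ax)^2 + (V / ay)^2 <= 1
}

#' Build the synthetic rat-abdomen digital phantom
#'
#' Ellipse-based compartment masks at anatomically plausible coronal
#' positions (liver, left/right kidney, chest/heart, a vascular strip, and
#' an external urea reference vial disjoint from all tissue), plus a smooth
#' band-limited random B0 off-resonance map. Construction is deterministic
#' for a given seed; mask positions and sizes receive a small seeded jitter.
#'
#' The chest compartment additionally carries a fixed B0 offset
#' (`chest_offset_hz`) placing it outside a metabolite-selective passband
#' while staying within a CSI peak-search window — a synthetic illustration
#' of chest signal appearing in spectroscopic but not selective imaging,
#' not a validated physiological mechanism.
#'
#' @param grid A [geometry2d()]; image grid of the phantom (coordinates in
#'   mm, FOV centered).
#' @param seed Integer seed; same seed gives a bit-identical phantom.
#' @param b0_rms Target RMS of the random B0 map inside the body (Hz).
#' @param b0_max Clamp for the random B0 map (Hz).
#' @param chest_offset_hz Fixed additional offset of the chest compartment
#'   (Hz).
#' @param params Phantom parameter list (`default_config()$phantom`); kinetic
#'   and amplitude parameters are carried into [hp_state()].
#' @return An object of class `digital_phantom`: `grid`, named logical
#'   `masks`, `b0_map` (Hz), per-compartment `kpl` and inflow amplitudes,
#'   `urea_amp`, `seed`.
#' @export
#' @examples
#' ph <- build_rat_phantom(geometry2d(c(64, 64), c(80, 80), 20), seed = 7)
#' sapply(ph$masks, sum)
build_rat_phantom <- function(grid = geometry2d(c(64L, 64L), c(80, 80), 20),
                              seed = 1L,
                              b0_rms = 15, b0_max = 60,
                              chest_offset_hz = 60,
                              params = default_config()$phantom) {
  nx <- grid$matrix[1]; ny <- grid$matrix[2]
  xs <- grid_coords_cm(nx, grid$fov[1]) * 10   # mm
  ys <- grid_coords_cm(ny, grid$fov[2]) * 10
  with_seed(seed, {
    j <- function(v, frac = 0.05) v * (1 + stats::runif(length(v), -frac, frac))
    body <- ellipse_mask(xs, ys, 0, -2, 26, 34)
    geo <- list(
      chest      = c(j(0), j(24), j(15), j(8)),
      liver      = c(j(-4), j(8), j(15), j(8)),
      kidney_L   = c(j(-13), j(-10), j(6), j(4.2)),
      kidney_R   = c(j(13), j(-10), j(6), j(4.2)),
      vasculature = c(j(0), j(-2), j(2.2), j(13))
    )
    raw <- lapply(names(geo), function(nm) {
      g <- geo[[nm]]
      ang <- if (nm == "liver") -0.25 else 0
      ellipse_mask(xs, ys, g[1], g[2], g[3], g[4], ang) & body
    })
    names(raw) <- names(geo)
    ## assign each voxel to the first matching compartment -> disjoint masks
    order_names <- c("chest", "liver", "kidney_L", "kidney_R", "vasculature")
    taken <- matrix(FALSE, nx, ny)
    masks <- list()
    for (nm in order_names) {
      m <- raw[[nm]] & !taken
      masks[[nm]] <- m
      taken <- taken | m
    }
    ## urea vial sits posterior to the body, outside all tissue
    vial <- ellipse_mask(xs, ys, 0, -36, 4, 3.2) & !body
    masks$urea_vial <- vial
    ## smooth random B0: white noise low-passed in k-space (gaussian),
    ## scaled to the target RMS inside the body, clamped, zero outside
    noise <- matrix(stats::rnorm(nx * ny), nx, ny)
    kx <- c(0:(nx %/% 2), -((ceiling(nx / 2) - 1):1)) / nx
    ky <- c(0:(ny %/% 2), -((ceiling(ny / 2) - 1):1)) / ny
    K2 <- outer(kx^2, rep(1, ny)) + outer(rep(1, nx), ky^2)
    filt <- exp(-K2 / (2 * (4 / nx)^2))
    smooth <- Re(stats::fft(stats::fft(noise) * filt, inverse = TRUE)) /
      (nx * ny)
    b0 <- smooth
    rms <- sqrt(mean(b0[body]^2))
    if (rms > 0 && b0_rms > 0) b0 <- b0 * (b0_rms / rms) else b0 <- b0 * 0
    b0 <- pmin(pmax(b0, -b0_max), b0_max)
    b0[!body] <- 0
    kpl <- c(chest = params$kpl_chest, liver = params$kpl_tissue,
             kidney_L = params$kpl_kidney, kidney_R = params$kpl_kidney,
             vasculature = 0)
    inflow_amp <- c(chest = 0.6, liver = 1.0, kidney_L = 1.2,
                    kidney_R = 1.2, vasculature = 2.0)
    structure(list(grid = grid, masks = masks, b0_map = b0,
                   chest_offset_hz = chest_offset_hz,
                   body = body, kpl = kpl, inflow_amp = inflow_amp,
                   urea_amp = params$urea_amp %||% 0.5,
                   params = params, seed = seed),
              class = "digital_phantom")
  })
}

#' @export
print.digital_phantom <- function(x, ...) {
  cat(sprintf("<digital_phantom> %dx%d grid, seed %d\n",
              x$grid$matrix[1], x$grid$matrix[2], x$seed))
  for (nm in names(x$masks))
    cat(sprintf("  %-12s %5d voxels\n", nm, sum(x$masks[[nm]])))
  cat(sprintf("  B0 map RMS (body) %.1f Hz\n", sqrt(mean(x$b0_map[x$body]^2))))
  invisible(x)
}

#' Gamma-variate arterial inflow function
#'
#' Normalized to unit peak at `peak_t`; zero for `t <= 0`.
#'
#' @param t Time since injection start (s); vectorized.
#' @param peak_t Time of the inflow peak (s).
#' @param shape Gamma-variate shape parameter (dimensionless).
#' @return Inflow rate (polarization units per second, unit peak).
#' @export
inflow_gamma <- function(t, peak_t = 12, shape = 2.5) {
  out <- numeric(length(t))
  pos <- t > 0
  x <- t[pos] / peak_t
  out[pos] <- x^shape * exp(shape * (1 - x))
  out
}

#' Initialize the hyperpolarized magnetization state of a phantom
#'
#' Creates the per-voxel, per-metabolite longitudinal magnetization state at
#' injection start (t = 0, all zero: magnetization arrives via the inflow
#' function). Pyruvate and lactate are the dynamic hyperpolarized species;
#' the urea vial is a thermal (constantly relaxed) reference handled by the
#' phantom itself.
#'
#' @param phantom A `digital_phantom`.
#' @param metab Metabolite table with T1 values; lactate T1 defaults to the
#'   phantom's configured value.
#' @param t1_lactate Lactate T1 override (s).
#' @return An object of class `hp_state`: `mz` (voxels x metabolites
#'   matrix), `t` (s), per-voxel `kpl` (1/s), inflow parameters.
#' @export
hp_state <- function(phantom, metab = metabolite_table(),
                     t1_lactate = phantom$params$t1_lactate %||% 33) {
  nvox <- prod(phantom$grid$matrix)
  mz <- matrix(0, nvox, 2, dimnames = list(NULL, c("pyruvate", "lactate")))
  kpl_map <- numeric(nvox)
  amp_map <- numeric(nvox)
  for (nm in setdiff(names(phantom$masks), "urea_vial")) {
    idx <- which(phantom$masks[[nm]])
    kpl_map[idx] <- phantom$kpl[[nm]]
    amp_map[idx] <- phantom$inflow_amp[[nm]]
  }
  structure(list(
    mz = mz, t = 0, kpl = kpl_map, inflow_amp = amp_map,
    t1 = c(pyruvate = met_row(metab, "pyruvate")$t1, lactate = t1_lactate),
    inflow_peak_t = phantom$params$inflow_peak_t %||% 12,
    inflow_shape = phantom$params$inflow_shape %||% 2.5,
    grid = phantom$grid), class = "hp_state")
}

#' @export
print.hp_state <- function(x, ...) {
  cat(sprintf("<hp_state> t = %.1f s, total Mz: pyruvate %.3g, lactate %.3g\n",
              x$t, sum(x$mz[, "pyruvate"]), sum(x$mz[, "lactate"])))
  invisible(x)
}

## One exact exponential-integrator step of the unidirectional two-site
## exchange with constant inflow i0 over the step:
##   dMp/dt = i0 - a Mp,  a = 1/T1p + kpl
##   dMl/dt = kpl Mp - b Ml,  b = 1/T1l
step_exchange <- function(mp, ml, kpl, a, b, i0, dt) {
  ea <- exp(-a * dt); eb <- exp(-b * dt)   # a vector (per voxel), b scalar
  cpart <- ifelse(a > 0, i0 / a, 0)        # asymptote under constant inflow
  mp_new <- ifelse(a > 0, cpart + (mp - cpart) * ea, mp + i0 * dt)
  ## lactate convolution integral, split into constant + exponential parts
  d <- mp - cpart
  ab <- b - a
  conv_exp <- ifelse(abs(ab) > 1e-12, (ea - eb) / ab, dt * ea)
  conv_const <- if (b > 0) cpart * (1 - eb) / b else cpart * dt
  ml_new <- ml * eb + kpl * (conv_const + d * conv_exp)
  list(mp = mp_new, ml = ml_new)
}

#' Evolve the hyperpolarized state through relaxation, exchange and inflow
#'
#' Unidirectional two-site exchange with T1 decay and a gamma-variate
#' pyruvate inflow, advanced by an exact exponential integrator per voxel.
#' The inflow rate is evaluated at substep midpoints (substeps of at most
#' 0.25 s while inflow is active); with zero inflow a single exact step is
#' taken regardless of `dt`.
#'
#' @param state An `hp_state`.
#' @param dt Time step (s), positive.
#' @param metab Unused placeholder kept for interface symmetry (T1 values
#'   are carried in the state).
#' @return The advanced `hp_state` with `t` increased by `dt`.
#' @export
evolve_hp_state <- function(state, dt, metab = NULL) {
  if (!is.numeric(dt) || dt < 0) stop("dt must be non-negative", call. = FALSE)
  if (dt == 0) return(state)
  a <- 1 / state$t1[["pyruvate"]] + state$kpl
  b <- 1 / state$t1[["lactate"]]
  has_inflow <- any(state$inflow_amp > 0)
  nsub <- if (has_inflow) max(1L, ceiling(dt / 0.25)) else 1L
  h <- dt / nsub
  mp <- state$mz[, "pyruvate"]; ml <- state$mz[, "lactate"]
  for (s in seq_len(nsub)) {
    tm <- state$t + (s - 0.5) * h
    i0 <- if (has_inflow)
      state$inflow_amp * inflow_gamma(tm, state$inflow_peak_t,
                                      state$inflow_shape)
    else 0
    upd <- step_exchange(mp, ml, state$kpl, a, b, i0, h)
    mp <- upd$mp; ml <- upd$ml
  }
  state$mz[, "pyruvate"] <- mp
  state$mz[, "lactate"] <- ml
  state$t <- state$t + dt
  state
}

#' Apply an RF excitation to one metabolite and collect its signal
#'
#' Per voxel the transverse signal is `mz * sin(flip * w)` and the remaining
#' longitudinal magnetization `mz * cos(flip * w)`, where `w` is the
#' excitation weight in `[0, 1]` (1 inside the slice/passband; from a Bloch
#' profile otherwise). Only the named metabolite is touched.
#'
#' @param state An `hp_state`.
#' @param metabolite Metabolite name present in the state.
#' @param flip Nominal flip angle (degrees, 0 to 180).
#' @param w Excitation weight: scalar or per-voxel vector in `[0, 1]`.
#' @return List with the updated `state` and the per-voxel transverse
#'   `signal` vector.
#' @export
apply_rf_consumption <- function(state, metabolite, flip, w = 1) {
  if (!metabolite %in% colnames(state$mz))
    stop("unknown metabolite: ", metabolite, call. = FALSE)
  stopifnot(flip >= 0, flip <= 180)
  th <- flip * w * pi / 180
  mz <- state$mz[, metabolite]
  signal <- mz * sin(th)
  state$mz[, metabolite] <- mz * cos(th)
  list(state = state, signal = signal)
}

#' Fit the pyruvate-to-lactate conversion rate from dynamic curves
#'
#' Least-squares estimate of the apparent unidirectional rate kPL from a
#' pair of pyruvate/lactate time curves: the lactate model
#' `dMl/dt = kPL * Mp(t) - Ml/T1l` is integrated exactly on the sampling
#' grid, driven by the (linearly interpolated) observed pyruvate curve, and
#' kPL minimizes the residual sum of squares against the observed lactate.
#'
#' @param t Sample times (s), strictly increasing.
#' @param pyruvate Observed pyruvate curve.
#' @param lactate Observed lactate curve.
#' @param t1_lactate Lactate T1 (s), assumed known.
#' @param interval Search interval for kPL (1/s).
#' @return An object of class `kpl_fit` with elements `kpl`, `fitted`,
#'   `residuals`, `rss`; methods: `coef`, `print`.
#' @export
#' @examples
#' ts <- seq(0, 40, by = 1)
#' mp <- exp(-ts / 30)
#' ml <- 0.03 * 30 * (exp(-ts / 33) - exp(-ts / 30)) / (1 / 30 - 1 / 33) / 30
#' # (use simulated curves in practice)
fit_kpl <- function(t, pyruvate, lactate, t1_lactate = 33,
                    interval = c(0, 0.5)) {
  stopifnot(length(t) == length(pyruvate), length(t) == length(lactate),
            !is.unsorted(t, strictly = TRUE))
  b <- 1 / t1_lactate
  ## exact step response for piecewise-linear Mp between samples
  predict_lac <- function(kpl) {
    ml <- numeric(length(t))
    for (i in seq_len(length(t) - 1)) {
      h <- t[i + 1] - t[i]
      m0 <- pyruvate[i]; m1 <- pyruvate[i + 1]
      slope <- (m1 - m0) / h
      eb <- exp(-b * h)
      ## integral of (m0 + slope*s) e^{-b(h-s)} ds, s in [0,h]
      I <- if (b > 0) {
        (m0 - slope / b) * (1 - eb) / b + slope * h / b
      } else {
        m0 * h + slope * h^2 / 2
      }
      ml[i + 1] <- ml[i] * eb + kpl * I
    }
    ml
  }
  rss <- function(kpl) sum((predict_lac(kpl) - lactate)^2)
  opt <- stats::optimize(rss, interval, tol = 1e-10)
  fitted <- predict_lac(opt$minimum)
  structure(list(kpl = opt$minimum, fitted = fitted,
                 residuals = lactate - fitted, rss = opt$objective,
                 t = t, t1_lactate = t1_lactate), class = "kpl_fit")
}

#' @export
coef.kpl_fit <- function(object, ...) c(kpl = object$kpl)

#' @export
print.kpl_fit <- function(x, ...) {
  cat(sprintf("<kpl_fit> kPL = %.5f 1/s (T1_lactate = %g s, RSS = %.3g)\n",
              x$kpl, x$t1_lactate, x$rss))
  invisible(x)
}
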