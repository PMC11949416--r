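# Synthetic M-B-mode elastography phantom: a quasi-harmonic surface wave
# radiating from a central excitation point, encoded as inter-A-line phase.

#' Ground-truth axial particle velocity field of an OCE phantom
#'
#' The wave is a square-windowed 1 kHz sinusoidal burst of `truth$n_cycles`
#' cycles travelling outward from the excitation point at `truth$wave_speed`,
#' with geometric spreading g(r) = sqrt(r_min / max(r, r_min)). r_min models
#' the excitation spot (0.3 mm); the estimator must be insensitive to the
#' exact decay law.
#'
#' @param truth a [phantom_truth()].
#' @param meta a [scan_metadata()]; lateral positions = `n_bscans`, time
#'   samples = `n_alines_per_bscan`.
#' @param r_min radius of the excitation spot (m); the decay law saturates
#'   inside it.
#' @return matrix \[lateral position, time\] of vz (m/s).
#' @export
oce_velocity_field <- function(truth, meta, r_min = 3e-4) {
  nx <- meta$n_bscans
  nt <- meta$n_alines_per_bscan
  x0 <- truth$excitation_position %||% ((nx + 1) %/% 2)
  f0 <- meta$excitation_frequency
  r <- abs(seq_len(nx) - x0) * meta$lateral_pixel_size        # m
  g <- sqrt(r_min / pmax(r, r_min))
  t <- (seq_len(nt) - 1) * meta$temporal_resolution           # s
  tau <- outer(-r / truth$wave_speed, t, `+`)                 # [nx, nt]
  w <- sin(2 * pi * f0 * tau)
  w[tau < 0 | tau >= truth$n_cycles / f0] <- 0
  truth$wave_amplitude * w * g
}

#' Generate an M-B-mode elastography phantom
#'
#' Builds static depth-resolved speckle (layered attenuation as in
#' [make_structural_phantom()]) at each lateral position and modulates its
#' phase so that the phase difference of consecutive A-lines encodes the
#' axial particle velocity of a travelling surface wave via
#' dphi = 4*pi*n*dt*vz/lambda0. Optional white phase noise per voxel and a
#' low-frequency breathing phase drift (continuous across the sequentially
#' acquired M-mode blocks) are added on top.
#'
#' @param truth a [phantom_truth()]; `wave_amplitude` must keep |dphi| < pi
#'   unless `allow_aliasing` is set.
#' @param meta a [scan_metadata()].
#' @param seed integer seed.
#' @param axis_label scan axis, `"lateral-medial"` or `"rostral-caudal"`.
#' @return object of class `mb_scan`: `data` is complex
#'   \[lateral position, time, depth\], plus metadata, excitation position,
#'   axis label and truth.
#' @export
make_oce_phantom <- function(truth, meta, seed,
                             axis_label = c("lateral-medial", "rostral-caudal")) {
  axis_label <- match.arg(axis_label)
  nx <- meta$n_bscans
  nt <- meta$n_alines_per_bscan
  nz <- meta$n_depth_pixels
  x0 <- truth$excitation_position %||% ((nx + 1) %/% 2)
  if (x0 < 1 || x0 > nx) mf_stop("excitation_position outside lateral range",
                                 "invalid_geometry")
  vz <- oce_velocity_field(truth, meta)
  peak_dphi <- 4 * pi * meta$refractive_index * meta$temporal_resolution *
    max(abs(vz)) / meta$central_wavelength
  if (peak_dphi >= pi && !isTRUE(truth$allow_aliasing)) {
    mf_stop(sprintf(
      "wave amplitude aliases the phase (peak |dphi| = %.2f rad >= pi); %s",
      peak_dphi, "set allow_aliasing = TRUE for deliberate aliasing tests"),
      "aliasing_configuration")
  }
  # cumulative displacement phase: dphi between A-lines k and k+1 equals
  # 4*pi*n*dt/lambda0 * vz at A-line k+1
  u <- meta$temporal_resolution * t(apply(vz, 1, cumsum))     # [nx, nt], m
  phase_xt <- 4 * pi * meta$refractive_index * u / meta$central_wavelength
  if (!is.null(truth$breathing) &&
      !is.null(truth$breathing$amplitude_rad) &&
      truth$breathing$amplitude_rad != 0) {
    fb <- truth$breathing$frequency_hz %||% 2
    block <- (seq_len(nx) - 1) * nt * meta$temporal_resolution
    tg <- outer(block, (seq_len(nt) - 1) * meta$temporal_resolution, `+`)
    phase_xt <- phase_xt + truth$breathing$amplitude_rad * sin(2 * pi * fb * tg)
  }
  sig <- speckle_sigma(truth, meta, nz, nx = nx, min_below = 4L)               # [nz, nx]
  n <- nx * nt * nz
  withr::with_seed(as.integer(seed), {
    s_static <- bandlimit_speckle(matrix(complex_speckle(nx * nz), nx, nz),
                                  rev(truth$speckle_grain_px)) * t(sig)
    # flat [nx*nt, nz] layout: row index varies x fastest, then t, matching
    # the array(dim = c(nx, nt, nz)) fill order
    phi <- matrix(phase_xt, nx * nt, nz)
    if (truth$phase_noise_sd > 0) {
      phi <- phi + stats::rnorm(n, 0, truth$phase_noise_sd)
    }
    data <- s_static[rep(seq_len(nx), nt), ] *
      complex(real = cos(phi), imaginary = sin(phi))
    if (truth$noise_floor_level > 0) {
      data <- data + truth$noise_floor_level * complex_speckle(n)
    }
    data <- array(data, dim = c(nx, nt, nz))
  })
  structure(list(data = data, metadata = meta,
                 excitation_position = x0, axis_label = axis_label,
                 truth = truth),
            class = "mb_scan")
}

#' @export
print.mb_scan <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("mb_scan (%s): %d lateral positions x %d time x %d depth\n",
              x$axis_label, d[1], d[2], d[3]))
  invisible(x)
}
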