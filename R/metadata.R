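#' Scan metadata for a swept-source OCT acquisition
#'
#' Bundles the acquisition parameters every analysis arm needs: the central
#' wavelength of the swept source, the inter-A-line interval (the temporal
#' resolution of phase-sensitive measurements), the sample refractive index
#' used to convert optical to tissue depth, pixel pitches, and the scan
#' geometry (A-lines per B-scan, B-scan positions, repeats per position).
#'
#' Defaults describe a 100 kHz swept source at 1300 nm imaging skin
#' (n = 1.42) over a 6.12 mm fast axis with 1000 A-lines, 1000 B-scan
#' positions, five repeats per position, and a 1 kHz mechanical excitation.
#' The default axial pitch in air (11.36 um) corresponds to an 8 um pitch in
#' tissue.
#'
#' @param central_wavelength central wavelength lambda0 (m).
#' @param temporal_resolution inter-A-line interval dt (s).
#' @param refractive_index sample refractive index n (>= 1).
#' @param axial_pixel_size_air axial pixel pitch in air (m); tissue pitch is
#'   this divided by `refractive_index`.
#' @param lateral_pixel_size lateral (fast-axis) pixel pitch (m).
#' @param slow_pixel_size slow-axis (B-scan position) pitch (m).
#' @param n_alines_per_bscan A-lines per B-scan (fast axis / time axis).
#' @param n_bscans B-scan positions (slow axis; lateral positions in M-B mode).
#' @param n_depth_pixels depth pixels per A-line.
#' @param repeats_per_position repeated B-scans at each slow-axis position.
#' @param excitation_frequency mechanical excitation frequency (Hz).
#' @return object of class `scan_metadata`.
#' @export
scan_metadata <- function(central_wavelength = 1.3e-6,
                          temporal_resolution = 1e-5,
                          refractive_index = 1.42,
                          axial_pixel_size_air = 1.136e-5,
                          lateral_pixel_size = 6.12e-6,
                          slow_pixel_size = 5.56e-6,
                          n_alines_per_bscan = 1000L,
                          n_bscans = 1000L,
                          n_depth_pixels = 500L,
                          repeats_per_position = 5L,
                          excitation_frequency = 1000) {
  m <- list(central_wavelength = central_wavelength,
            temporal_resolution = temporal_resolution,
            refractive_index = refractive_index,
            axial_pixel_size_air = axial_pixel_size_air,
            lateral_pixel_size = lateral_pixel_size,
            slow_pixel_size = slow_pixel_size,
            n_alines_per_bscan = as.integer(n_alines_per_bscan),
            n_bscans = as.integer(n_bscans),
            n_depth_pixels = as.integer(n_depth_pixels),
            repeats_per_position = as.integer(repeats_per_position),
            excitation_frequency = excitation_frequency)
  for (f in c("central_wavelength", "temporal_resolution",
              "axial_pixel_size_air", "lateral_pixel_size",
              "slow_pixel_size", "excitation_frequency")) {
    if (!is.numeric(m[[f]]) || length(m[[f]]) != 1 || !is.finite(m[[f]]) ||
        m[[f]] <= 0) {
      mf_stop(sprintf("metadata field '%s' must be a positive scalar", f),
              "invalid_metadata")
    }
  }
  if (m$refractive_index < 1) {
    mf_stop("refractive_index must be >= 1", "invalid_metadata")
  }
  for (f in c("n_alines_per_bscan", "n_bscans", "n_depth_pixels",
              "repeats_per_position")) {
    if (m[[f]] < 1L) mf_stop(sprintf("'%s' must be >= 1", f), "invalid_metadata")
  }
  structure(m, class = "scan_metadata")
}

#' Axial pixel pitch in tissue (m)
#' @param meta a `scan_metadata`.
#' @export
tissue_pitch <- function(meta) meta$axial_pixel_size_air / meta$refractive_index

#' Largest axial particle velocity representable without phase wrapping
#'
#' The inter-A-line phase shift is 4*pi*n*dt*vz/lambda0; |dphi| = pi maps to
#' the aliasing ceiling lambda0 / (4*n*dt) (about 22.9 mm/s at the defaults).
#'
#' @param meta a `scan_metadata`.
#' @return velocity ceiling (m/s).
#' @export
aliasing_velocity <- function(meta) {
  meta$central_wavelength /
    (4 * meta$refractive_index * meta$temporal_resolution)
}

#' @export
print.scan_metadata <- function(x, ...) {
  cat(sprintf(
    "scan_metadata: lambda0=%.0f nm, dt=%.1f us, n=%.2f, %d x %d x %d px, %d repeats\n",
    x$central_wavelength * 1e9, x$temporal_resolution * 1e6,
    x$refractive_index, x$n_bscans, x$n_depth_pixels, x$n_alines_per_bscan,
    x$repeats_per_position))
  invisible(x)
}

#' Ground-truth parameters of a synthetic phantom
#'
#' Collects every quantity the analysis arms later estimate, so recovery can
#' be checked against construction: the surface depth profile, the
#' epidermis-dermis junction (EDJ) depth, the attenuation slope of the
#' log-intensity A-line, the surface-wave speed and amplitude, vessel
#' geometry, inter-repeat bulk motion, breathing motion, and noise levels.
#'
#' @param surface_depth_index depth index of the tissue surface, scalar or
#'   one value per lateral position (1-based pixels).
#' @param edj_depth EDJ depth below the surface (m), or `NULL` for phantoms
#'   without a visible junction.
#' @param attenuation_slope depth decay of the dB A-line in tissue (dB/mm,
#'   negative).
#' @param wave_speed surface-wave propagation speed (m/s).
#' @param wave_amplitude peak axial particle velocity of the wave (m/s). The
#'   default 5 mm/s keeps the inter-A-line phase shift well below pi.
#' @param n_cycles cycles in the 1 kHz excitation burst.
#' @param excitation_position lateral index of the excitation point; `NULL`
#'   means the scan centre.
#' @param vessel_set list of vessels, each
#'   `list(centerline = 2-column matrix of (bscan, lateral) pixel vertices,
#'   depth_um = depth of the axis below the surface, diameter_um = lumen
#'   diameter)`.
#' @param bulk_shifts repeats x 2 matrix of per-repeat (axial, lateral)
#'   sub-pixel displacements, or `NULL` for none.
#' @param breathing `list(amplitude_px=, frequency_hz=, positions=)`:
#'   low-frequency motion; `positions` are slow-axis indices that receive the
#'   large, depth-dependent displacement that produces stripe artefacts.
#'   For M-B-mode phantoms `amplitude_rad` sets the phase-drift amplitude.
#' @param noise_floor_level linear amplitude of the additive detection noise.
#' @param signal_level linear amplitude scale of the tissue speckle at the
#'   surface.
#' @param phase_noise_sd SD (rad) of white phase noise per voxel.
#' @param speckle_grain_px (axial, lateral) speckle grain in pixels, the
#'   correlation length the point-spread function imposes on the speckle
#'   (see [bandlimit_speckle()]); values <= 1 give per-voxel white speckle.
#' @param edj_contrast multiplicative amplitude dip of the EDJ band.
#' @param allow_aliasing set `TRUE` only for deliberate aliasing tests.
#' @return object of class `phantom_truth`.
#' @export
phantom_truth <- function(surface_depth_index = 60L,
                          edj_depth = NULL,
                          attenuation_slope = -0.057,
                          wave_speed = 1.2,
                          wave_amplitude = 5e-3,
                          n_cycles = 5L,
                          excitation_position = NULL,
                          vessel_set = list(),
                          bulk_shifts = NULL,
                          breathing = NULL,
                          noise_floor_level = 1e-3,
                          signal_level = 1,
                          phase_noise_sd = 0,
                          speckle_grain_px = c(1.5, 2),
                          edj_contrast = 0.3,
                          allow_aliasing = FALSE) {
  if (any(surface_depth_index < 1)) {
    mf_stop("surface_depth_index must be >= 1", "invalid_geometry")
  }
  if (wave_speed <= 0) mf_stop("wave_speed must be > 0", "invalid_truth")
  if (!is.null(bulk_shifts)) bulk_shifts <- as.matrix(bulk_shifts)
  structure(list(surface_depth_index = surface_depth_index,
                 edj_depth = edj_depth,
                 attenuation_slope = attenuation_slope,
                 wave_speed = wave_speed,
                 wave_amplitude = wave_amplitude,
                 n_cycles = as.integer(n_cycles),
                 excitation_position = excitation_position,
                 vessel_set = vessel_set,
                 bulk_shifts = bulk_shifts,
                 breathing = breathing,
                 noise_floor_level = noise_floor_level,
                 signal_level = signal_level,
                 phase_noise_sd = phase_noise_sd,
                 speckle_grain_px = speckle_grain_px,
                 edj_contrast = edj_contrast,
                 allow_aliasing = allow_aliasing),
            class = "phantom_truth")
}

#' Phase-noise SD giving a target phase SNR
#'
#' Phase SNR is defined as the ratio, in dB, of the peak inter-A-line phase
#' shift produced by the wave to the SD of the inter-A-line phase noise.
#' White phase noise of SD sigma per A-line yields difference noise of SD
#' sigma*sqrt(2), hence the sqrt(2) below.
#'
#' @param truth a `phantom_truth`.
#' @param meta a `scan_metadata`.
#' @param snr_db target phase SNR in dB.
#' @return per-voxel phase noise SD (rad).
#' @export
phase_noise_for_snr <- function(truth, meta, snr_db) {
  peak_dphi <- 4 * pi * meta$refractive_index * meta$temporal_resolution *
    abs(truth$wave_amplitude) / meta$central_wavelength
  peak_dphi * 10^(-snr_db / 20) / sqrt(2)
}
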