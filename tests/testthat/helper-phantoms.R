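# Compact scan geometries and truth builders shared across tests.
# Physics fields (wavelength, timing, refractive index, pitches) are the
# instrument values; grid extents are kept small so tests run quickly.

small_oce_meta <- function(nx = 61L, nt = 1000L, nz = 34L, pitch = 5e-5) {
  scan_metadata(n_bscans = nx, n_alines_per_bscan = nt, n_depth_pixels = nz,
                lateral_pixel_size = pitch, repeats_per_position = 1L)
}

power_oce_meta <- function() {
  scan_metadata(n_bscans = 41L, n_alines_per_bscan = 700L,
                n_depth_pixels = 30L, lateral_pixel_size = 5e-5,
                repeats_per_position = 1L)
}

small_structural_meta <- function(nx = 200L, nz = 360L) {
  scan_metadata(n_bscans = 1L, n_alines_per_bscan = nx, n_depth_pixels = nz,
                repeats_per_position = 5L)
}

small_octa_meta <- function(nb = 40L, nx = 100L, nz = 60L) {
  scan_metadata(n_bscans = nb, n_alines_per_bscan = nx, n_depth_pixels = nz,
                repeats_per_position = 5L)
}

oce_truth <- function(speed = 1.5, snr_db = NULL, meta = small_oce_meta(),
                      ...) {
  tr <- phantom_truth(surface_depth_index = 8L, wave_speed = speed,
                      noise_floor_level = if (is.null(snr_db)) 0 else 1e-3,
                      ...)
  if (!is.null(snr_db)) {
    tr$phase_noise_sd <- phase_noise_for_snr(tr, meta, snr_db)
  }
  tr
}

vessel_truth <- function(diameter_um = 105, meta = small_octa_meta(),
                         bulk_shifts = rbind(c(0, 0), c(0.4, -0.6),
                                             c(1.2, 2.1), c(-0.8, 1.4),
                                             c(2.5, -3)), ...) {
  phantom_truth(
    surface_depth_index = 12L,
    vessel_set = list(list(
      centerline = cbind(c(1, meta$n_bscans),
                         rep((meta$n_alines_per_bscan + 1) / 2, 2)),
      depth_um = 140, diameter_um = diameter_um)),
    bulk_shifts = bulk_shifts, ...)
}

# dB image of the repeat-averaged central B-scan of a volume
central_db_image <- function(volume) {
  avg <- average_repeats(volume)
  nb <- dim(avg$intensity)[1]
  to_db(avg$intensity[(nb + 1L) %/% 2L, , ])
}
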