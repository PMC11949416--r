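# Synthetic structural phantom: fully-developed speckle over a layered
# attenuation profile, with an optional EDJ band and an additive noise floor.

#' Amplitude scale (speckle sigma) per voxel for a layered skin phantom
#'
#' Above the surface the tissue amplitude is zero (detection noise only).
#' Below it the expected log-magnitude decays linearly with tissue depth at
#' `truth$attenuation_slope` dB/mm; the EDJ, when present, is a thin band of
#' reduced amplitude.
#'
#' @noRd
speckle_sigma <- function(truth, meta, nz, nx, min_below = 20L) {
  surf <- rep_len(as.numeric(truth$surface_depth_index), nx)
  if (max(surf) + min_below > nz) {
    mf_stop("depth range too small to contain the surface plus a decay region",
            "invalid_geometry")
  }
  dz_mm <- tissue_pitch(meta) * 1e3
  z <- seq_len(nz)
  depth_mm <- outer(z, surf, function(zi, s) (zi - s) * dz_mm)  # [nz, nx]
  sig <- truth$signal_level * 10^(truth$attenuation_slope * depth_mm / 20)
  sig[depth_mm < 0] <- 0
  if (!is.null(truth$edj_depth)) {
    edj_px <- truth$edj_depth / tissue_pitch(meta)
    band <- depth_mm / dz_mm  # depth in pixels below surface
    in_band <- band >= (edj_px - 1) & band <= (edj_px + 1)
    sig[in_band] <- sig[in_band] * truth$edj_contrast
  }
  sig
}

#' Generate a structural OCT phantom volume
#'
#' Produces a complex volume of fully-developed speckle (circularly-symmetric
#' complex Gaussian per voxel) whose ensemble-mean dB A-line decays linearly
#' below the tissue surface at the ground-truth attenuation slope, over an
#' additive complex-Gaussian noise floor. Repeats and B-scan positions carry
#' independent speckle, so magnitude averaging over repeats improves image
#' quality the way repeated in vivo B-scans do.
#'
#' @param truth a [phantom_truth()]; `attenuation_slope` must be negative.
#' @param meta a [scan_metadata()]; array dimensions come from its counts.
#' @param seed integer seed; the phantom is a pure function of
#'   (truth, meta, seed).
#' @return object of class `complex_volume`: `data` is a complex array
#'   indexed \[repeat, bscan, depth, lateral\], plus `metadata` and `truth`.
#' @export
make_structural_phantom <- function(truth, meta, seed) {
  if (truth$attenuation_slope >= 0) {
    mf_stop("attenuation_slope must be negative", "invalid_truth")
  }
  nr <- meta$repeats_per_position
  nb <- meta$n_bscans
  nz <- meta$n_depth_pixels
  nx <- meta$n_alines_per_bscan
  sig <- speckle_sigma(truth, meta, nz, nx)  # errors if geometry invalid
  grain <- truth$speckle_grain_px
  withr::with_seed(as.integer(seed), {
    data <- array(complex(real = 0), dim = c(nr, nb, nz, nx))
    for (b in seq_len(nb)) {
      for (r in seq_len(nr)) {
        frame <- bandlimit_speckle(matrix(complex_speckle(nz * nx), nz, nx),
                                   grain) * sig
        data[r, b, , ] <- frame +
          truth$noise_floor_level * complex_speckle(nz * nx)
      }
    }
  })
  structure(list(data = data, metadata = meta, truth = truth),
            class = "complex_volume")
}

#' @export
print.complex_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("complex_volume: %d repeats x %d bscans x %d depth x %d lateral\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}
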