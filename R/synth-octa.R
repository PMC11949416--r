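# Synthetic repeated-B-scan angiography phantom: static speckle reused
# across repeats, fully decorrelating speckle inside vessel tubes, sub-pixel
# bulk motion between repeats, and breathing-corrupted positions that
# produce stripe artefacts.

#' Vessel cross-section mask for one B-scan position
#'
#' Vessels are tubes defined by an en-face centerline polyline (vertices in
#' (bscan, lateral) pixels), a depth below the surface and a lumen diameter.
#' The slice mask is the set of (depth, lateral) pixels within the lumen
#' radius of the interpolated centerline, measured in physical units.
#'
#' @param truth a [phantom_truth()] with a `vessel_set`.
#' @param meta a [scan_metadata()].
#' @param bscan slow-axis index of the slice.
#' @return logical matrix \[depth, lateral\].
#' @export
vessel_mask_slice <- function(truth, meta, bscan) {
  nz <- meta$n_depth_pixels
  nx <- meta$n_alines_per_bscan
  mask <- matrix(FALSE, nz, nx)
  if (length(truth$vessel_set) == 0) return(mask)
  dz_um <- tissue_pitch(meta) * 1e6
  dx_um <- meta$lateral_pixel_size * 1e6
  surf <- rep_len(as.numeric(truth$surface_depth_index), nx)
  z_um <- outer(seq_len(nz), rep(1, nx)) * dz_um
  x_idx <- seq_len(nx)
  for (v in truth$vessel_set) {
    cl <- v$centerline
    if (bscan < min(cl[, 1]) || bscan > max(cl[, 1])) next
    cx <- stats::approx(cl[, 1], cl[, 2], xout = bscan, rule = 2)$y
    zc_px <- mean(surf) + v$depth_um / dz_um
    r_um <- v$diameter_um / 2
    if (zc_px - r_um / dz_um < 1 || zc_px + r_um / dz_um > nz ||
        cx - r_um / dx_um < 1 || cx + r_um / dx_um > nx) {
      mf_stop("vessel tube extends outside the volume", "invalid_geometry")
    }
    d2 <- outer(((seq_len(nz) - zc_px) * dz_um)^2,
                ((x_idx - cx) * dx_um)^2, `+`)
    mask <- mask | (d2 <= r_um^2)
  }
  mask
}

#' Shift a frame laterally with a depth-dependent (shearing) displacement
#'
#' Models large, non-rigid breathing motion that rigid registration cannot
#' undo: each depth row is spectrally shifted along the lateral axis by a
#' displacement that grows linearly with depth.
#' @noRd
shear_shift <- function(frame, disp_px) {
  nz <- nrow(frame); nx <- ncol(frame)
  fr <- fft_freq(nx)
  disp <- disp_px * (0.5 + seq_len(nz) / nz)  # per-depth displacement
  ramp <- exp(-2i * pi * outer(disp, fr))
  t(stats::mvfft(stats::mvfft(t(frame)) * t(ramp), inverse = TRUE)) / nx
}

#' Per-repeat breathing displacement of an angiography phantom
#'
#' The breathing model is a low-frequency sinusoid sampled at the
#' instrument's B-scan cadence (`frame_period`, default 10 ms): repeat `r`
#' at position `b` is displaced laterally (with a depth-dependent shear) by
#' `amplitude_px * sin(2*pi*f*t + 0.7)` where `t` counts acquired frames.
#' Positions not listed in `breathing$positions` are unaffected. A position
#' sampled near a breathing extremum moves little between its repeats and
#' therefore decorrelates little — exactly as in vivo.
#'
#' @param truth a [phantom_truth()].
#' @param meta a [scan_metadata()].
#' @return matrix \[n_bscans, repeats\] of lateral displacements (px).
#' @export
breathing_displacements <- function(truth, meta) {
  nb <- meta$n_bscans; nr <- meta$repeats_per_position
  out <- matrix(0, nb, nr)
  br <- truth$breathing
  if (is.null(br) || is.null(br$positions) || (br$amplitude_px %||% 0) == 0) {
    return(out)
  }
  fp <- br$frame_period %||% 1e-2
  f <- br$frequency_hz %||% 2
  for (b in as.integer(br$positions)) {
    tg <- ((b - 1) * nr + (seq_len(nr) - 1)) * fp
    out[b, ] <- br$amplitude_px * sin(2 * pi * f * tg + 0.7)
  }
  out
}

#' Generate a repeated-B-scan angiography phantom
#'
#' Static tissue voxels reuse the same speckle realization in every repeat
#' (perfect inter-repeat correlation apart from detection noise); voxels
#' inside vessel tubes are redrawn independently per repeat (full
#' decorrelation, emulating moving blood). Each repeat can then be displaced
#' by a sub-pixel bulk shift, and a configurable subset of B-scan positions
#' receives large depth-dependent breathing displacement that rigid
#' registration cannot correct, producing the familiar stripe artefacts.
#'
#' @inheritParams make_structural_phantom
#' @return a `complex_volume` with `data` indexed
#'   \[repeat, bscan, depth, lateral\].
#' @export
make_octa_phantom <- function(truth, meta, seed) {
  nr <- meta$repeats_per_position
  if (nr < 2) mf_stop("repeats_per_position must be >= 2 for angiography",
                      "invalid_metadata")
  nb <- meta$n_bscans
  nz <- meta$n_depth_pixels
  nx <- meta$n_alines_per_bscan
  sig <- speckle_sigma(truth, meta, nz, nx)
  shifts <- truth$bulk_shifts
  if (!is.null(shifts) && nrow(shifts) != nr) {
    mf_stop("bulk_shifts must have one row per repeat", "invalid_truth")
  }
  br_disp <- breathing_displacements(truth, meta)
  withr::with_seed(as.integer(seed), {
    data <- array(complex(real = 0), dim = c(nr, nb, nz, nx))
    for (b in seq_len(nb)) {
      static <- bandlimit_speckle(matrix(complex_speckle(nz * nx), nz, nx),
                                  truth$speckle_grain_px) * sig
      vmask <- vessel_mask_slice(truth, meta, b)
      nflow <- sum(vmask)
      for (r in seq_len(nr)) {
        frame <- static
        if (nflow > 0) {
          flow <- bandlimit_speckle(matrix(complex_speckle(nz * nx), nz, nx),
                                    truth$speckle_grain_px) * sig
          frame[vmask] <- flow[vmask]
        }
        if (!is.null(shifts) && any(shifts[r, ] != 0)) {
          frame <- fourier_shift(frame, shifts[r, ])
        }
        if (br_disp[b, r] != 0) {
          frame <- shear_shift(frame, br_disp[b, r])
        }
        frame <- frame + truth$noise_floor_level * complex_speckle(nz * nx)
        data[r, b, , ] <- frame
      }
    }
  })
  structure(list(data = data, metadata = meta, truth = truth),
            class = "complex_volume")
}

#' True en-face vessel footprint of a phantom
#'
#' @param truth,meta as in [make_octa_phantom()].
#' @return logical matrix \[bscan, lateral\]: columns of the volume that
#'   intersect a vessel tube.
#' @export
vessel_footprint <- function(truth, meta) {
  nb <- meta$n_bscans
  t(vapply(seq_len(nb),
           function(b) apply(vessel_mask_slice(truth, meta, b), 2, any),
           logical(meta$n_alines_per_bscan)))
}
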