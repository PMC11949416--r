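# Elastography arm: phase-sensitive particle velocity, excitation-band
# filtering, spatiotemporal maps and robust wave-speed estimation.

#' Arrival time (in samples, 1-based) of a wave packet from its envelope:
#' the energy centroid of the contiguous half-maximum region around the
#' envelope peak. The centroid is insensitive to the carrier ripple that
#' makes the raw peak location lock onto carrier maxima.
#' @noRd
envelope_arrival <- function(e) {
  p <- which.max(e)
  th <- e[p] / 2
  l <- p; while (l > 1 && e[l - 1] >= th) l <- l - 1
  r <- p; while (r < length(e) && e[r + 1] >= th) r <- r + 1
  w <- e[l:r]^2
  sum((l:r) * w) / sum(w)
}

#' Inter-A-line phase difference of an M-B-mode scan
#'
#' For each lateral position and depth, the argument of the product of each
#' A-line with the complex conjugate of its predecessor, wrapped to
#' (-pi, pi]. The time dimension shrinks by one.
#'
#' @param mb an `mb_scan` with complex data \[lateral, time, depth\].
#' @return array \[lateral, time - 1, depth\] of phase differences (rad).
#' @export
phase_difference <- function(mb) {
  d <- dim(mb$data)
  if (d[2] < 2) mf_stop("need at least two A-lines in time", "invalid_input")
  a <- mb$data[, -1, , drop = FALSE] * Conj(mb$data[, -d[2], , drop = FALSE])
  Arg(a)
}

#' Convert phase differences to axial particle velocity
#'
#' vz = dphi * lambda0 / (4 * pi * n * dt): the phase-sensitive Doppler
#' relation between the inter-A-line phase shift and the axial velocity of
#' the scatterers.
#'
#' @param dphi phase-difference array from [phase_difference()] (rad).
#' @param meta a [scan_metadata()].
#' @return list of class `velocity_field`: `vz` (m/s, same shape as `dphi`)
#'   and `metadata`.
#' @export
phase_to_velocity <- function(dphi, meta) {
  vz <- dphi * meta$central_wavelength /
    (4 * pi * meta$refractive_index * meta$temporal_resolution)
  structure(list(vz = vz, metadata = meta), class = "velocity_field")
}

#' Zero-phase band-pass at the excitation frequency
#'
#' 4th-order Butterworth design with passband `f0` +/- `half_width`, applied
#' forward and backward (zero phase). Isolates the quasi-harmonic excitation
#' from low-frequency physiological motion such as breathing.
#'
#' @param trace numeric vector, or matrix whose columns are traces.
#' @param f0 excitation frequency (Hz).
#' @param sample_rate sampling rate (Hz); must exceed 2*(f0 + half_width).
#' @param half_width half-width of the passband (Hz).
#' @param order Butterworth order.
#' @param pad zeros prepended and appended before filtering (and cropped
#'   after). The narrow band has a long impulse response, so the filter's
#'   edge transients would otherwise leak into the trace and bias arrival
#'   times; padding keeps the filtering shift-invariant.
#' @return filtered trace(s), same shape.
#' @export
bandpass_excitation <- function(trace, f0, sample_rate, half_width = 200,
                                order = 4, pad = NULL) {
  lo <- f0 - half_width; hi <- f0 + half_width
  if (lo <= 0 || hi >= sample_rate / 2) {
    mf_stop("passband infeasible for this sample rate", "filter_design")
  }
  bf <- signal::butter(order, c(lo, hi) / (sample_rate / 2), type = "pass")
  one <- function(x) {
    n <- length(x)
    np <- pad %||% n
    # constant-edge padding: shift-invariant for transient traces (their
    # edges are at rest) without the broadband step a hard zero pad would
    # introduce on slowly varying signals
    y <- signal::filtfilt(bf, c(rep(x[1], np), x, rep(x[n], np)))
    y[(np + 1):(np + n)]
  }
  if (is.matrix(trace)) apply(trace, 2, one) else one(trace)
}

#' Build a lateral-position x time spatiotemporal map
#'
#' For every lateral position, the band-passed particle velocity is averaged
#' over a depth window below the detected surface (170 um of tissue by
#' default). The band-pass is linear, so averaging the depth window first
#' and filtering the averaged trace once per position is mathematically
#' identical to filtering each depth and then averaging, and much cheaper.
#'
#' @param field a `velocity_field` (vz indexed \[lateral, time, depth\]).
#' @param profile a `surface_profile` for the scan (per lateral position).
#' @param depth_window depth window below the surface (m of tissue).
#' @param excitation_position lateral index of the excitation.
#' @param f0 excitation frequency (Hz); defaults to the metadata value.
#' @return object of class `st_map`: `values` \[lateral, time\],
#'   `lateral_pitch` (m), `time_pitch` (s), `excitation_position`.
#' @export
build_st_map <- function(field, profile, depth_window = 170e-6,
                         excitation_position, f0 = NULL) {
  meta <- field$metadata
  d <- dim(field$vz)
  nx <- d[1]; nt <- d[2]; nz <- d[3]
  win_px <- max(1L, as.integer(round(depth_window / tissue_pitch(meta))))
  surf <- rep_len(profile$surface_index, nx)
  if (any(surf + win_px > nz)) {
    mf_stop("depth window extends beyond the imaging depth", "invalid_window")
  }
  vals <- matrix(0, nx, nt)
  for (j in seq_len(nx)) {
    vals[j, ] <- rowMeans(field$vz[j, , surf[j]:(surf[j] + win_px), drop = TRUE])
  }
  f0 <- f0 %||% meta$excitation_frequency
  fs <- 1 / meta$temporal_resolution
  vals <- t(bandpass_excitation(t(vals), f0 = f0, sample_rate = fs))
  structure(list(values = vals,
                 lateral_pitch = meta$lateral_pixel_size,
                 time_pitch = meta$temporal_resolution,
                 excitation_position = excitation_position),
            class = "st_map")
}

#' Robust wave-speed estimate from a spatiotemporal map
#'
#' Per lateral position, the wave arrival time is the (parabolically
#' refined) peak of the envelope of the band-passed velocity trace. On each
#' side of the excitation, arrival time is regressed on distance with
#' iteratively reweighted least squares (bisquare weights); the side speed
#' is the inverse slope. Sides are fitted independently, gated on fit R^2,
#' and averaged.
#'
#' @param map an `st_map`.
#' @param min_positions minimum usable lateral positions per side.
#' @param exclusion_radius distance around the excitation excluded from the
#'   fit (m); the near field of the source is not a propagating plane wave.
#' @param amplitude_gate positions whose envelope peak is below this
#'   fraction of the map's strongest envelope are dropped as too weak.
#' @param r2_gate sides with weighted fit R^2 below this are dropped.
#' @return object of class `wave_speed_result`: `speed` (m/s),
#'   `per_side_speeds`, `fit_r2`, `inlier_fraction`, `n_positions`.
#' @export
fit_wave_speed <- function(map, min_positions = 10L, exclusion_radius = 3e-4,
                           amplitude_gate = 0.15, r2_gate = 0.5) {
  nx <- nrow(map$values)
  x0 <- map$excitation_position
  env <- t(apply(map$values, 1, analytic_envelope))
  peak_amp <- apply(env, 1, max)
  arrival <- apply(env, 1, envelope_arrival) * map$time_pitch
  dist <- abs(seq_len(nx) - x0) * map$lateral_pitch
  usable <- dist > exclusion_radius & peak_amp > amplitude_gate * max(peak_amp)
  sides <- list(left = which(seq_len(nx) < x0 & usable),
                right = which(seq_len(nx) > x0 & usable))
  n_ok <- vapply(sides, length, integer(1))
  if (all(n_ok < min_positions)) {
    mf_stop("fewer than the minimum usable lateral positions on both sides",
            "insufficient_extent")
  }
  fit_side <- function(idx) {
    if (length(idx) < min_positions) return(NULL)
    x <- dist[idx]; y <- arrival[idx]
    if (stats::sd(y) == 0) {
      mf_stop("identical arrival times: no propagating wave found",
              "propagation_not_found")
    }
    ols <- stats::lm.fit(cbind(1, x), y)
    if (sqrt(mean(ols$residuals^2)) < 1e-12) {
      cf <- ols$coefficients
      w <- rep(1, length(x))
    } else {
      # tight tolerance rarely converges in 50 IRLS steps; the slope change
      # in the final steps is far below the estimator noise, so the
      # convergence warning carries no information here
      rf <- suppressWarnings(MASS::rlm(y ~ x, psi = MASS::psi.bisquare,
                                       maxit = 50, acc = 1e-9))
      cf <- stats::coef(rf)
      w <- rf$w
    }
    slope <- cf[2]
    if (!is.finite(slope) || slope <= 0) {
      mf_stop("nonpositive space-time slope: no propagating wave found",
              "propagation_not_found")
    }
    yhat <- cf[1] + slope * x
    r2 <- 1 - sum(w * (y - yhat)^2) / sum(w * (y - stats::weighted.mean(y, w))^2)
    list(speed = 1 / slope, r2 = r2, inlier = mean(w > 0.5))
  }
  fits <- lapply(sides, fit_side)
  keep <- !vapply(fits, is.null, logical(1))
  r2s <- vapply(fits[keep], `[[`, numeric(1), "r2")
  gated <- r2s >= r2_gate
  if (!any(gated)) {
    mf_stop("all sides fail the fit-quality gate", "propagation_not_found")
  }
  if (!all(gated)) {
    mf_warn("dropping a side with fit R^2 below the quality gate", "side_dropped")
  }
  good <- fits[keep][gated]
  speeds <- vapply(good, `[[`, numeric(1), "speed")
  per_side <- c(left = NA_real_, right = NA_real_)
  per_side[names(fits)[keep][gated]] <- speeds
  structure(list(speed = mean(speeds),
                 per_side_speeds = per_side,
                 fit_r2 = mean(vapply(good, `[[`, numeric(1), "r2")),
                 inlier_fraction = mean(vapply(good, `[[`, numeric(1), "inlier")),
                 n_positions = sum(n_ok)),
            class = "wave_speed_result")
}

#' @export
print.wave_speed_result <- function(x, ...) {
  cat(sprintf("wave speed: %.3f m/s (left %.3f, right %.3f; R2 %.3f, inliers %.0f%%)\n",
              x$speed, x$per_side_speeds[1], x$per_side_speeds[2],
              x$fit_r2, 100 * x$inlier_fraction))
  invisible(x)
}

#' Average wave speeds measured on different scan axes
#'
#' @param results list of `wave_speed_result` (or bare speeds in m/s).
#' @return arithmetic mean speed (m/s).
#' @export
average_axes <- function(results) {
  if (length(results) == 0) mf_stop("no valid axis results", "no_valid_axes")
  speeds <- vapply(results, function(r) {
    if (inherits(r, "wave_speed_result")) r$speed else as.numeric(r)
  }, numeric(1))
  mean(speeds)
}

#' Run the full elastography arm on one M-B-mode scan
#'
#' Computes phase differences, converts to particle velocity, detects the
#' surface from the time-averaged magnitude image, builds the spatiotemporal
#' map over a depth window below the surface, and fits the wave speed.
#'
#' @param mb an `mb_scan`.
#' @param depth_window_um depth-averaging window (um of tissue).
#' @param noise_rows topmost air rows for surface statistics.
#' @param ... passed to [fit_wave_speed()].
#' @return a `wave_speed_result`.
#' @export
oce_pipeline <- function(mb, depth_window_um = 170, noise_rows = 5, ...) {
  dphi <- phase_difference(mb)
  field <- phase_to_velocity(dphi, mb$metadata)
  # time-averaged magnitude image, [depth, lateral]
  mag_db <- to_db(t(colMeans(aperm(Mod(mb$data), c(2, 1, 3)))))
  prof <- detect_surface(mag_db, noise_rows = noise_rows)
  map <- build_st_map(field, prof, depth_window = depth_window_um * 1e-6,
                      excitation_position = mb$excitation_position)
  fit_wave_speed(map, ...)
}
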