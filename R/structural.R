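# Structural arm: repeat averaging, boundary tracking and the OCT signal
# slope (OCTSS) over the dermis.

#' Average repeated B-scans by magnitude
#'
#' Repeats acquired at the same position are averaged on magnitude (not as
#' complex fields, which would be destroyed by phase drift between repeats),
#' improving image quality before boundary tracking and slope fitting.
#'
#' @param volume a `complex_volume` indexed \[repeat, bscan, depth, lateral\].
#' @return list with `intensity` (array \[bscan, depth, lateral\] of averaged
#'   magnitudes) and `metadata`.
#' @export
average_repeats <- function(volume) {
  d <- dim(volume$data)
  m <- Mod(volume$data)
  avg <- colMeans(array(m, dim = c(d[1], prod(d[2:4]))))
  list(intensity = array(avg, dim = d[2:4]), metadata = volume$metadata)
}

#' Track the tissue surface in a dB B-scan
#'
#' Noise statistics are estimated from the topmost air rows; each A-line is
#' median-filtered along depth and the surface is the first pixel exceeding
#' noise mean + `threshold_factor` * noise SD. The profile is then smoothed
#' laterally with a running median to suppress single-A-line dropouts.
#'
#' @param bscan_db dB image, matrix \[depth, lateral\].
#' @param threshold_factor multiple of the noise SD above the noise mean.
#' @param noise_rows number of topmost rows guaranteed to be air; reduce for
#'   shallow scans.
#' @param smooth_window lateral running-median window (odd).
#' @return object of class `surface_profile` with fields `surface_index`,
#'   `dermis_start_index`, `noise_floor_index`, `provenance`.
#' @export
detect_surface <- function(bscan_db, threshold_factor = 4, noise_rows = 30,
                           smooth_window = 15) {
  nz <- nrow(bscan_db); nx <- ncol(bscan_db)
  noise_rows <- min(noise_rows, nz - 1L)
  noise <- bscan_db[seq_len(noise_rows), , drop = FALSE]
  thr <- mean(noise) + threshold_factor * stats::sd(noise)
  med_k <- min(5L, nz - (1 - nz %% 2))
  surf <- vapply(seq_len(nx), function(j) {
    a <- stats::runmed(bscan_db[, j], med_k)
    idx <- which(a > thr)
    idx <- idx[idx > noise_rows]   # ignore spurious hits inside the air gap
    if (length(idx) == 0) NA_integer_ else idx[1]
  }, integer(1))
  if (all(is.na(surf))) {
    mf_stop("no A-line crosses the surface threshold", "surface_not_found")
  }
  if (anyNA(surf)) {
    surf[is.na(surf)] <- as.integer(round(stats::median(surf, na.rm = TRUE)))
  }
  k <- min(smooth_window, nx - (1 - nx %% 2))
  if (k >= 3) surf <- as.integer(round(stats::runmed(surf, k)))
  structure(list(surface_index = surf,
                 dermis_start_index = surf,
                 noise_floor_index = nz,
                 provenance = "detected"),
            class = "surface_profile")
}

#' Find the depth at which signal decays into the noise floor
#'
#' Returns the deepest index at which the laterally-averaged dB intensity
#' remains above noise mean + 3 * noise SD, scanning the contiguous
#' above-threshold run downward from the brightest row. Data below this
#' index are excluded from slope fits.
#'
#' @inheritParams detect_surface
#' @return depth index; `0` when nothing rises above the noise, the last
#'   index (with a warning) when the signal never decays into the noise.
#' @export
detect_noise_floor <- function(bscan_db, noise_rows = 30) {
  nz <- nrow(bscan_db)
  noise_rows <- min(noise_rows, nz - 1L)
  prof <- rowMeans(bscan_db)
  noise <- prof[seq_len(noise_rows)]
  thr <- mean(noise) + 3 * stats::sd(noise)
  above <- prof > thr
  if (!any(above)) return(0L)
  peak <- which.max(prof)
  if (!above[peak]) return(0L)
  idx <- peak
  while (idx < nz && above[idx + 1]) idx <- idx + 1L
  if (idx == nz) {
    mf_warn("signal never decays to the noise floor; using the last depth index",
            "no_noise_floor")
  }
  idx
}

#' Locate the epidermis-dermis junction (EDJ) below the surface
#'
#' Searches a band below the detected surface for a local intensity minimum
#' on each laterally-smoothed A-line. An A-line reports the junction only
#' when the dip prominence (flanking maxima minus the minimum) exceeds
#' `min_prominence_db`; absence is a valid outcome (fibrotic skin loses the
#' junction) and the caller then substitutes a fallback dermis depth.
#'
#' @param bscan_db dB image \[depth, lateral\].
#' @param profile a `surface_profile`.
#' @param meta a [scan_metadata()] (for the depth scale).
#' @param search_um band below the surface to search, (min, max) in um of
#'   tissue depth.
#' @param min_prominence_db prominence floor for accepting a dip.
#' @param min_fraction minimum fraction of A-lines with an accepted dip for
#'   the junction to count as detected.
#' @return integer vector of per-lateral EDJ depth indices, or `NULL` when
#'   the junction is not detected.
#' @export
detect_edj <- function(bscan_db, profile, meta,
                       search_um = c(20, 120), min_prominence_db = 2,
                       min_fraction = 0.5) {
  nz <- nrow(bscan_db); nx <- ncol(bscan_db)
  dz_um <- tissue_pitch(meta) * 1e6
  lo <- pmax(1L, as.integer(round(search_um[1] / dz_um)))
  hi <- as.integer(round(search_um[2] / dz_um))
  # lateral smoothing to tame speckle before looking for a thin dark band
  sm <- t(apply(bscan_db, 1, function(r) {
    k <- min(31L, nx - (1 - nx %% 2)); if (k >= 3) stats::runmed(r, k) else r
  }))
  edj <- rep(NA_integer_, nx)
  for (j in seq_len(nx)) {
    s <- profile$surface_index[min(j, length(profile$surface_index))]
    band <- (s + lo):min(s + hi, nz)
    if (length(band) < 5) next
    # no depth-wise smoothing: the junction is only a few pixels thick and a
    # median filter along depth would erase it
    a <- sm[band, j]
    k <- which.min(a)
    if (k <= 1 || k >= length(a)) next
    prom <- min(max(a[1:(k - 1)]), max(a[(k + 1):length(a)])) - a[k]
    if (is.finite(prom) && prom >= min_prominence_db) edj[j] <- band[k]
  }
  if (mean(!is.na(edj)) < min_fraction) return(NULL)
  fill <- as.integer(round(stats::median(edj, na.rm = TRUE)))
  edj[is.na(edj)] <- fill
  edj
}

#' Attach the dermis start to a surface profile
#'
#' When the EDJ was detected its indices become the dermis start; otherwise
#' a fallback dermis depth (a configured constant, conventionally the cohort
#' average of detected EDJ depths) is used below the surface.
#'
#' @param profile a `surface_profile`.
#' @param edj per-lateral EDJ indices from [detect_edj()], or `NULL`.
#' @param fallback_um fallback dermis depth below the surface (um of tissue),
#'   used when `edj` is `NULL`.
#' @param meta a [scan_metadata()].
#' @param below_junction_px offset added below the junction (or below the
#'   fallback depth) so the fit window starts in clean dermis rather than on
#'   the dark junction band itself.
#' @return updated `surface_profile` with `provenance` set to `"detected"`
#'   or `"fallback-average"`.
#' @export
set_dermis_start <- function(profile, edj, meta, fallback_um = 60,
                             below_junction_px = 2L) {
  if (is.null(edj)) {
    off <- as.integer(round(fallback_um / (tissue_pitch(meta) * 1e6)))
    profile$dermis_start_index <- profile$surface_index + off + below_junction_px
    profile$provenance <- "fallback-average"
  } else {
    profile$dermis_start_index <- pmax(edj + below_junction_px,
                                       profile$surface_index)
    profile$provenance <- "detected"
  }
  profile
}

#' OCT signal slope (OCTSS) over the dermis
#'
#' Fits, for every A-line, an ordinary least-squares line to dB intensity
#' versus physical tissue depth (axial air pitch divided by the refractive
#' index) over the window from the dermis start to the noise floor, and
#' averages the per-A-line slopes. Units are dB/mm.
#'
#' @param bscan_db dB image \[depth, lateral\].
#' @param profile a `surface_profile` whose `dermis_start_index` and
#'   `noise_floor_index` bound the fit.
#' @param meta a [scan_metadata()].
#' @param min_samples minimum depth samples required in the fit window.
#' @return object of class `octss_result`: `per_aline_slope` (dB/mm),
#'   `mean_slope`, `fit_depth_range`, `n_alines_used`, `r2_mean`,
#'   `dermis_provenance`.
#' @export
compute_octss <- function(bscan_db, profile, meta, min_samples = 20L) {
  nz <- nrow(bscan_db); nx <- ncol(bscan_db)
  dstart <- rep_len(profile$dermis_start_index, nx)
  nf <- profile$noise_floor_index
  dz_mm <- tissue_pitch(meta) * 1e3
  slopes <- rep(NA_real_, nx)
  r2 <- rep(NA_real_, nx)
  for (j in seq_len(nx)) {
    win <- dstart[j]:(nf - 1L)
    if (length(win) < min_samples) next
    y <- bscan_db[win, j]
    x <- win * dz_mm
    xc <- x - mean(x); yc <- y - mean(y)
    sxx <- sum(xc^2)
    b <- sum(xc * yc) / sxx
    slopes[j] <- b
    ssr <- sum((yc - b * xc)^2)
    sst <- sum(yc^2)
    r2[j] <- if (sst > 0) 1 - ssr / sst else 1
  }
  used <- which(!is.na(slopes))
  if (length(used) == 0) {
    mf_stop(sprintf("fit window shorter than %d samples on every A-line",
                    min_samples), "insufficient_depth")
  }
  structure(list(per_aline_slope = slopes,
                 mean_slope = mean(slopes[used]),
                 fit_depth_range = c(min(dstart), nf),
                 n_alines_used = length(used),
                 r2_mean = mean(r2[used]),
                 dermis_provenance = profile$provenance),
            class = "octss_result")
}

#' @export
print.octss_result <- function(x, ...) {
  cat(sprintf("OCTSS: %.4f dB/mm over %d A-lines (mean R2 %.3f, dermis %s)\n",
              x$mean_slope, x$n_alines_used, x$r2_mean, x$dermis_provenance))
  invisible(x)
}

#' Run the full structural arm on one volume
#'
#' Averages repeats, takes the central B-scan position, converts to dB,
#' tracks surface and noise floor, locates (or falls back past) the EDJ, and
#' fits the OCTSS.
#'
#' @param volume a `complex_volume`.
#' @param fallback_dermis_um dermis start below the surface when the EDJ is
#'   not detected (um of tissue).
#' @param noise_rows topmost rows used for air-noise statistics.
#' @param threshold_factor surface threshold factor.
#' @param central_frames how many central B-scan positions to average into
#'   the image that is fitted.
#' @return an `octss_result`.
#' @export
octss_pipeline <- function(volume, fallback_dermis_um = 60, noise_rows = 30,
                           threshold_factor = 4, central_frames = 1L) {
  avg <- average_repeats(volume)
  nb <- dim(avg$intensity)[1]
  ctr <- (nb + 1L) %/% 2L
  half <- (central_frames - 1L) %/% 2L
  sel <- max(1L, ctr - half):min(nb, ctr + half)
  img <- apply(avg$intensity[sel, , , drop = FALSE], c(2, 3), mean)
  db <- to_db(img)
  prof <- detect_surface(db, threshold_factor = threshold_factor,
                         noise_rows = noise_rows)
  prof$noise_floor_index <- max(detect_noise_floor(db, noise_rows = noise_rows),
                                max(prof$surface_index) + 21L)
  edj <- detect_edj(db, prof, volume$metadata)
  prof <- set_dermis_start(prof, edj, volume$metadata,
                           fallback_um = fallback_dermis_um)
  prof$dermis_start_index <- pmin(prof$dermis_start_index,
                                  prof$noise_floor_index - 21L)
  compute_octss(db, prof, volume$metadata)
}
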