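# Angiography arm (cm-OCA): sub-pixel registration, inter-repeat
# correlation mapping, SNR-aware masking, pair rejection, stripe filtering,
# en-face projection and lumen measurement.

#' Upsampled inverse DFT of a cross-power spectrum over a small region
#'
#' Evaluates the correlation surface at lags ((i-1) - roff)/usfac,
#' ((j-1) - coff)/usfac by matrix-multiply DFT, the standard sub-pixel
#' refinement kernel.
#' @noRd
dft_upsample <- function(X, nor, noc, usfac, roff, coff) {
  nr <- nrow(X); nc <- ncol(X)
  fr <- fft_freq(nr) * nr
  fc <- fft_freq(nc) * nc
  kernr <- exp((2i * pi / (nr * usfac)) * outer((seq_len(nor) - 1) - roff, fr))
  kernc <- exp((2i * pi / (nc * usfac)) * outer(fc, (seq_len(noc) - 1) - coff))
  kernr %*% X %*% kernc
}

#' Sub-pixel registration of a repeated B-scan pair
#'
#' Finds the (axial, lateral) shift maximizing the magnitude
#' cross-correlation via the FFT, refines it to 1/`upsample` pixel with a
#' locally upsampled discrete Fourier transform, and resamples the second
#' frame onto the first by the negated shift (spectral shift on the complex
#' data).
#'
#' @param frame_a,frame_b complex (or real) B-scan matrices \[depth, lateral\]
#'   of equal shape.
#' @param upsample sub-pixel refinement factor (>= 1; 20 gives 1/20 px).
#' @return list with `shift` (axial, lateral, in pixels: how far `frame_b`
#'   is displaced relative to `frame_a`) and `registered` (frame_b shifted
#'   back into alignment).
#' @export
register_pair <- function(frame_a, frame_b, upsample = 20L) {
  if (!all(dim(frame_a) == dim(frame_b))) {
    mf_stop("frames must have equal shapes", "invalid_input")
  }
  a <- Mod(frame_a); b <- Mod(frame_b)
  if (all(a == 0) || all(b == 0)) {
    mf_stop("registration undefined for all-zero frames", "registration_undefined")
  }
  nr <- nrow(a); nc <- ncol(a)
  Fa <- stats::fft(a); Fb <- stats::fft(b)
  cps <- Conj(Fa) * Fb
  cc <- Re(stats::fft(cps, inverse = TRUE)) / (nr * nc)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  sr <- pk[1] - 1; sc <- pk[2] - 1
  if (sr > nr / 2) sr <- sr - nr
  if (sc > nc / 2) sc <- sc - nc
  if (upsample > 1) {
    # refine in a 1.5 px neighbourhood of the integer peak
    usfac <- as.integer(upsample)
    nor <- ceiling(usfac * 1.5); noc <- nor
    roff <- floor(nor / 2) - sr * usfac
    coff <- floor(noc / 2) - sc * usfac
    cc_up <- Mod(dft_upsample(cps, nor, noc, usfac, roff, coff))
    pku <- which(cc_up == max(cc_up), arr.ind = TRUE)[1, ]
    sr <- ((pku[1] - 1) - floor(nor / 2)) / usfac + sr
    sc <- ((pku[2] - 1) - floor(noc / 2)) / usfac + sc
  }
  shift <- c(axial = sr, lateral = sc)
  list(shift = shift, registered = fourier_shift(frame_b, -shift))
}

#' Box-filter local mean (periodic boundary, via FFT)
#' @noRd
box_mean <- function(img, kernel) {
  k <- matrix(1 / prod(kernel), kernel[1], kernel[2])
  EBImage::filter2(img, k, boundary = "circular")
}

#' Inter-repeat correlation map
#'
#' For each consecutive pair of registered magnitude B-scans, the zero-mean
#' normalized cross-correlation (ZNCC) within a sliding kernel around each
#' pixel; the per-pixel mean over the pairs is returned. Static tissue
#' correlates near 1, flowing blood decorrelates.
#'
#' @param repeats list of registered magnitude B-scans \[depth, lateral\].
#' @param kernel odd (depth, lateral) window dimensions.
#' @param pair_weights optional logical keep-mask over consecutive pairs
#'   (from [reject_pairs()]); rejected pairs are excluded from the average.
#' @param global_rows depth rows over which the per-pair global correlation
#'   is averaged (defaults to the whole frame; pass the tissue rows to keep
#'   air noise out of the rejection statistic).
#' @param return_pairs also return the per-pair correlation maps.
#' @return list: `correlation` (matrix, clamped to \[-1, 1\]),
#'   `pair_correlations` (global mean ZNCC per pair), `n_pairs_used`, and
#'   optionally `pair_maps`.
#' @export
correlation_map <- function(repeats, kernel = c(5L, 5L), pair_weights = NULL,
                            global_rows = NULL, return_pairs = FALSE) {
  if (length(repeats) < 2) mf_stop("need at least two repeats", "invalid_input")
  if (any(kernel %% 2 == 0)) mf_stop("kernel dimensions must be odd",
                                     "invalid_kernel")
  dm <- dim(repeats[[1]])
  if (any(kernel > dm)) mf_stop("kernel larger than the frame", "invalid_kernel")
  npair <- length(repeats) - 1
  keep <- pair_weights %||% rep(TRUE, npair)
  gr <- global_rows %||% seq_len(dm[1])
  acc <- matrix(0, dm[1], dm[2])
  pc <- numeric(npair)
  maps <- if (return_pairs) vector("list", npair) else NULL
  used <- 0L
  eps <- .Machine$double.eps
  for (p in seq_len(npair)) {
    a <- repeats[[p]]; b <- repeats[[p + 1]]
    ma <- box_mean(a, kernel); mb <- box_mean(b, kernel)
    va <- pmax(box_mean(a * a, kernel) - ma^2, 0)
    vb <- pmax(box_mean(b * b, kernel) - mb^2, 0)
    cov <- box_mean(a * b, kernel) - ma * mb
    r <- cov / sqrt(va * vb + eps)
    r <- pmin(pmax(r, -1), 1)
    pc[p] <- mean(r[gr, ])
    if (return_pairs) maps[[p]] <- r
    if (keep[p]) {
      acc <- acc + r
      used <- used + 1L
    }
  }
  if (used == 0L) mf_stop("all pairs rejected at this position", "all_rejected")
  out <- list(correlation = acc / used, pair_correlations = pc,
              n_pairs_used = used)
  if (return_pairs) out$pair_maps <- maps
  out
}

#' SNR-dependent correction of a decorrelation map
#'
#' Converts correlation to decorrelation (1 - correlation, clamped to
#' \[0, 1\]) and masks pixels whose intensity sits within `k` noise SDs of
#' the depth-resolved noise mean: below the sensitivity floor, decorrelation
#' is noise, not flow, and is set to 0.
#'
#' @param correlation correlation matrix \[depth, lateral\].
#' @param intensity_db averaged dB B-scan of the same shape.
#' @param noise_profile list with `mean` and `sd`, scalars or per-depth
#'   vectors (see [noise_profile_from_air()]).
#' @param k gate width in noise SDs.
#' @return decorrelation matrix in \[0, 1\] with sub-noise pixels zeroed.
#' @export
snr_correct <- function(correlation, intensity_db, noise_profile, k = 3) {
  if (is.null(noise_profile$mean) || is.null(noise_profile$sd)) {
    mf_stop("noise profile must provide mean and sd", "noise_estimation")
  }
  dec <- pmin(pmax(1 - correlation, 0), 1)
  thr <- rep_len(noise_profile$mean, nrow(intensity_db)) +
    k * rep_len(noise_profile$sd, nrow(intensity_db))
  dec[intensity_db < thr] <- 0
  dec
}

#' Depth-resolved noise statistics from the air gap above the tissue
#'
#' @param intensity_db dB B-scan \[depth, lateral\].
#' @param profile a `surface_profile`; rows above `min(surface) - margin`
#'   are treated as air.
#' @param margin rows of guard band kept below the air region.
#' @return list with scalar `mean` and `sd` of the air intensity (dB).
#' @export
noise_profile_from_air <- function(intensity_db, profile, margin = 3L) {
  top <- min(profile$surface_index) - margin
  if (top < 2) mf_stop("no air region above the surface to estimate noise",
                       "noise_estimation")
  air <- intensity_db[seq_len(top), , drop = FALSE]
  list(mean = mean(air), sd = stats::sd(as.vector(air)))
}

#' Mean-minus-SD rejection of decorrelated B-scan pairs
#'
#' The threshold is mean minus sample SD (denominator n - 1) of the global
#' per-pair correlations; pairs strictly below it (typically corrupted by
#' large breathing motion) are excluded from the pair average.
#'
#' @param global_correlations numeric vector of per-pair global correlations.
#' @return list: `keep` (logical), `threshold`, `n_rejected`.
#' @export
reject_pairs <- function(global_correlations) {
  if (length(global_correlations) < 2) {
    mf_stop("need at least two pairs to form a rejection threshold",
            "invalid_input")
  }
  thr <- mean(global_correlations) - stats::sd(global_correlations)
  keep <- global_correlations >= thr
  if (!any(keep)) mf_stop("all pairs rejected", "all_rejected")
  list(keep = keep, threshold = thr, n_rejected = sum(!keep))
}

#' Frequency-rejection filter for breathing stripes
#'
#' Breathing corrupts whole B-scan positions, leaving stripes along the fast
#' axis of the en-face image, i.e. energy concentrated at (near-)zero
#' fast-axis frequency. The filter zeroes spectral coefficients with
#' |fast-axis frequency| below `width` bins at all nonzero slow-axis
#' frequencies, preserves DC, and leaves everything else untouched.
#'
#' @param enface 2D en-face image \[slow, fast\].
#' @param width half-width of the rejected fast-axis frequency band, in
#'   frequency bins.
#' @return filtered image, same shape.
#' @export
stripe_filter <- function(enface, width = 1L) {
  nr <- nrow(enface); nc <- ncol(enface)
  Fm <- stats::fft(enface)
  f_fast <- abs(fft_freq(nc)) * nc   # bins
  f_slow <- abs(fft_freq(nr)) * nr
  kill <- outer(f_slow != 0, f_fast < width, `&`)
  Fm[kill] <- 0
  Re(stats::fft(Fm, inverse = TRUE)) / (nr * nc)
}

#' Maximum-intensity projection of a decorrelation volume
#'
#' @param decorr array \[bscan, depth, lateral\] of decorrelation values.
#' @param surface per-position surface depth index (scalar, vector per
#'   lateral position, or matrix \[bscan, lateral\]).
#' @param noise_floor deepest depth index included.
#' @param margin rows below the surface excluded (the bright surface line
#'   itself decorrelates with any residual motion).
#' @return en-face matrix \[bscan, lateral\] of depth maxima.
#' @export
mip_enface <- function(decorr, surface, noise_floor = dim(decorr)[2],
                       margin = 2L) {
  d <- dim(decorr)
  surf <- if (is.matrix(surface)) surface else
    matrix(rep_len(as.numeric(surface), d[3]), d[1], d[3], byrow = TRUE)
  out <- matrix(0, d[1], d[3])
  for (b in seq_len(d[1])) {
    for (j in seq_len(d[3])) {
      z0 <- min(surf[b, j] + margin, noise_floor)
      out[b, j] <- max(decorr[b, z0:noise_floor, j])
    }
  }
  out
}

#' Lumen diameter of the largest vessel in an en-face angiogram
#'
#' Binarizes the en-face decorrelation image (Otsu threshold by default),
#' keeps the largest connected component, traces its centerline (centroids
#' of cross-slices along the component's principal axis), and reports the
#' maximum over centerline points of the full width at half maximum (FWHM)
#' of the decorrelation profile along the local normal, converted to um.
#'
#' @param mip en-face decorrelation image \[slow, fast\] in \[0, 1\].
#' @param pitches (slow, fast) pixel pitches (m).
#' @param threshold binarization threshold; `NULL` for Otsu.
#' @param exclude_rows slow-axis rows to ignore (e.g. rejected breathing
#'   positions).
#' @return object of class `vessel_measurement`: `lumen_diameter_um`,
#'   `profile_width_px`, `measurement_location`, `threshold`.
#' @export
measure_lumen <- function(mip, pitches, threshold = NULL,
                          exclude_rows = integer(0)) {
  # excluded (breathing-corrupted) rows carry no reliable data; filling
  # them from the nearest clean rows keeps vessels connected across the
  # stripe instead of splitting them into stubby fragments
  work <- mip
  if (length(exclude_rows) > 0) {
    ok <- setdiff(seq_len(nrow(mip)), exclude_rows)
    if (length(ok) == 0) mf_stop("no usable en-face rows", "no_vessel_found")
    for (r in exclude_rows) {
      lo <- ok[ok < r]; hi <- ok[ok > r]
      src <- c(if (length(lo)) max(lo), if (length(hi)) min(hi))
      work[r, ] <- colMeans(mip[src, , drop = FALSE])
    }
  }
  thr <- threshold %||% EBImage::otsu(EBImage::Image(pmin(pmax(work, 0), 1)))
  mask <- work > thr
  if (!any(mask)) mf_stop("no vessel found above the threshold", "no_vessel_found")
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  tab <- tabulate(as.integer(lab[lab > 0]))
  comp <- which.max(tab)
  mask <- matrix(as.integer(lab) == comp, nrow(mip), ncol(mip))
  px <- which(mask, arr.ind = TRUE)
  # physical coordinates (m) of component pixels
  P <- cbind(px[, 1] * pitches[1], px[, 2] * pitches[2])
  ctr <- colMeans(P)
  axis1 <- eigen(stats::cov(P))$vectors[, 1]  # along-vessel direction
  slice_centerline <- function(axis1) {
    s <- as.vector(sweep(P, 2, ctr) %*% axis1)
    nbin <- max(5L, as.integer(round(diff(range(s)) / max(pitches))))
    bins <- cut(s, breaks = nbin, labels = FALSE)
    do.call(rbind, lapply(split(seq_along(s), bins), function(i) {
      colMeans(P[i, , drop = FALSE])
    }))
  }
  # two passes: on short, wide components the first principal axis can tilt
  # and skew the slice centroids; refitting the axis to the first-pass
  # centerline straightens it
  cl <- slice_centerline(axis1)
  if (nrow(cl) >= 3) {
    axis1 <- svd(sweep(cl, 2, colMeans(cl)))$v[, 1]
    cl <- slice_centerline(axis1)
  }
  # trim the component's end caps where cross-slices are foreshortened
  ntrim <- max(1L, nrow(cl) %/% 10L)
  cl <- cl[(1 + ntrim):(nrow(cl) - ntrim), , drop = FALSE]
  if (nrow(cl) < 2) mf_stop("vessel too short to trace", "no_vessel_found")
  # smooth the centerline: centroid noise tilts the local normal, and an
  # oblique cut overestimates the width by 1/cos(theta)
  if (nrow(cl) >= 7) {
    sm5 <- function(v) {
      f <- stats::filter(v, rep(1 / 5, 5), sides = 2)
      f[is.na(f)] <- v[is.na(f)]
      as.numeric(f)
    }
    cl <- cbind(sm5(cl[, 1]), sm5(cl[, 2]))
  }
  step <- min(pitches) / 4
  # generous half-length: twice the mean component width plus a margin
  extent <- diff(range(as.vector(sweep(P, 2, ctr) %*% axis1)))
  width_m <- sum(mask) * pitches[1] * pitches[2] / max(extent, step)
  half_len <- 2 * width_m + 6 * max(pitches)
  offs <- seq(-half_len, half_len, by = step)
  interp <- function(y, x) {          # bilinear sample of work at (row, col)
    r <- y / pitches[1]; c <- x / pitches[2]
    r0 <- floor(r); c0 <- floor(c)
    if (r0 < 1 || c0 < 1 || r0 + 1 > nrow(work) || c0 + 1 > ncol(work)) return(0)
    fr <- r - r0; fc <- c - c0
    work[r0, c0] * (1 - fr) * (1 - fc) + work[r0 + 1, c0] * fr * (1 - fc) +
      work[r0, c0 + 1] * (1 - fr) * fc + work[r0 + 1, c0 + 1] * fr * fc
  }
  best <- list(w = 0, at = c(NA, NA))
  navg <- 2L  # profiles averaged over +/- navg skeleton points to tame speckle
  for (i in seq_len(nrow(cl))) {
    lo <- max(1L, i - 5L); hi <- min(nrow(cl), i + 5L)
    tang <- cl[hi, ] - cl[lo, ]
    tang <- tang / sqrt(sum(tang^2))
    nrm <- c(-tang[2], tang[1])
    pts <- max(1L, i - navg):min(nrow(cl), i + navg)
    prof <- rowMeans(vapply(pts, function(k) {
      vapply(offs, function(o) {
        q <- cl[k, ] + o * nrm
        interp(q[1], q[2])
      }, numeric(1))
    }, numeric(length(offs))))
    pk <- max(prof)
    if (pk <= 0) next
    # half height above the pedestal: the en-face background is a noisy
    # nonzero baseline, and a plain half-maximum would count it as vessel
    ntail <- max(2L, length(offs) %/% 8L)
    base <- stats::median(c(utils::head(prof, ntail), utils::tail(prof, ntail)))
    th <- base + (pk - base) / 2
    above <- prof >= th
    ctr_i <- which.max(prof)
    l <- ctr_i; while (l > 1 && above[l - 1]) l <- l - 1
    r <- ctr_i; while (r < length(prof) && above[r + 1]) r <- r + 1
    w <- (r - l) * step
    if (w > best$w) best <- list(w = w, at = cl[i, ])
  }
  if (best$w == 0) mf_stop("no measurable profile on the vessel", "no_vessel_found")
  structure(list(lumen_diameter_um = best$w * 1e6,
                 profile_width_px = best$w / pitches[2],
                 measurement_location = best$at,
                 threshold = thr),
            class = "vessel_measurement")
}

#' @export
print.vessel_measurement <- function(x, ...) {
  cat(sprintf("largest vessel lumen: %.1f um (threshold %.3f)\n",
              x$lumen_diameter_um, x$threshold))
  invisible(x)
}

#' Run the full angiography arm on one repeated-B-scan volume
#'
#' Registers the repeats at every B-scan position to the first repeat,
#' computes per-pair global correlations, applies volume-wide mean-minus-SD
#' pair rejection, averages the kept pairs' ZNCC maps, converts to SNR-masked
#' decorrelation, projects below the surface, filters breathing stripes, and
#' measures the largest vessel's lumen.
#'
#' @param volume a `complex_volume` \[repeat, bscan, depth, lateral\].
#' @param kernel ZNCC window (depth, lateral), odd.
#' @param snr_k SNR gate width in noise SDs.
#' @param upsample registration refinement factor.
#' @param noise_rows topmost air rows for surface statistics.
#' @param stripe_width fast-axis band half-width for [stripe_filter()].
#' @param measure if `FALSE`, skip lumen measurement (e.g. static phantoms).
#' @return object of class `angiogram`: `decorrelation`
#'   \[bscan, depth, lateral\], `mip`, `mip_filtered`, `vessel` (a
#'   `vessel_measurement` or `NULL`), `rejected_pairs` (matrix of
#'   (position, pair)), `rejected_positions`, `threshold_used`, `surface`.
#' @export
octa_pipeline <- function(volume, kernel = c(5L, 5L), snr_k = 3,
                          upsample = 20L, noise_rows = 30L, stripe_width = 1L,
                          measure = TRUE) {
  d <- dim(volume$data)
  nr <- d[1]; nb <- d[2]; nz <- d[3]; nx <- d[4]
  meta <- volume$metadata
  # registered frames, per-pair correlation maps and surfaces, per position
  pair_maps <- vector("list", nb)
  pair_corr <- matrix(NA_real_, nb, nr - 1)
  intensity_db <- vector("list", nb)
  surface <- matrix(NA_real_, nb, nx)
  for (b in seq_len(nb)) {
    frames <- lapply(seq_len(nr), function(r) volume$data[r, b, , ])
    regs <- vector("list", nr)
    regs[[1]] <- frames[[1]]
    for (r in 2:nr) {
      regs[[r]] <- register_pair(frames[[1]], frames[[r]],
                                 upsample = upsample)$registered
    }
    mags <- lapply(regs, Mod)
    img_db <- to_db(Reduce(`+`, mags) / nr)
    intensity_db[[b]] <- img_db
    prof <- detect_surface(img_db, noise_rows = noise_rows)
    surface[b, ] <- prof$surface_index
    tissue_rows <- min(nz, max(prof$surface_index) + 2L):nz
    cm <- correlation_map(mags, kernel = kernel, global_rows = tissue_rows,
                          return_pairs = TRUE)
    pair_corr[b, ] <- cm$pair_correlations
    pair_maps[[b]] <- cm$pair_maps
  }
  rej <- reject_pairs(as.vector(pair_corr))
  keep <- matrix(rej$keep, nb, nr - 1)
  rejected_pairs <- which(!keep, arr.ind = TRUE)
  colnames(rejected_pairs) <- c("position", "pair")
  decorr <- array(0, dim = c(nb, nz, nx))
  rejected_positions <- integer(0)
  for (b in seq_len(nb)) {
    if (!any(keep[b, ])) {
      rejected_positions <- c(rejected_positions, b)
      next
    }
    corr <- Reduce(`+`, pair_maps[[b]][keep[b, ]]) / sum(keep[b, ])
    prof_b <- structure(list(surface_index = surface[b, ]),
                        class = "surface_profile")
    np <- noise_profile_from_air(intensity_db[[b]], prof_b)
    decorr[b, , ] <- snr_correct(corr, intensity_db[[b]], np, k = snr_k)
  }
  nf <- max(vapply(seq_len(nb),
                   function(b) detect_noise_floor(intensity_db[[b]],
                                                  noise_rows = noise_rows),
                   integer(1)))
  if (nf <= 0) nf <- nz
  # light slow-axis averaging before projection: the depth maximum would
  # otherwise ride on the upper tail of the ZNCC noise, inflating vessel
  # halos in proportion to the vessel's depth extent
  decorr_s <- decorr
  ok_pos <- setdiff(seq_len(nb), rejected_positions)
  np <- length(ok_pos)
  if (np >= 5) {
    sub <- decorr[ok_pos, , , drop = FALSE]
    w5 <- sub
    w5[3:(np - 2), , ] <- (sub[1:(np - 4), , , drop = FALSE] +
                           sub[2:(np - 3), , , drop = FALSE] +
                           sub[3:(np - 2), , , drop = FALSE] +
                           sub[4:(np - 1), , , drop = FALSE] +
                           sub[5:np, , , drop = FALSE]) / 5
    decorr_s[ok_pos, , ] <- w5
  } else if (np >= 3) {
    sub <- decorr[ok_pos, , , drop = FALSE]
    w3 <- sub
    w3[2:(np - 1), , ] <- (sub[1:(np - 2), , , drop = FALSE] +
                           sub[2:(np - 1), , , drop = FALSE] +
                           sub[3:np, , , drop = FALSE]) / 3
    decorr_s[ok_pos, , ] <- w3
  }
  mip <- mip_enface(decorr_s, surface, noise_floor = min(nf, nz))
  mip_f <- stripe_filter(mip, width = stripe_width)
  vessel <- NULL
  if (measure) {
    vessel <- measure_lumen(pmin(pmax(mip_f, 0), 1),
                            pitches = c(meta$slow_pixel_size,
                                        meta$lateral_pixel_size),
                            exclude_rows = rejected_positions)
  }
  structure(list(decorrelation = decorr, mip = mip, mip_filtered = mip_f,
                 vessel = vessel, rejected_pairs = rejected_pairs,
                 rejected_positions = rejected_positions,
                 threshold_used = rej$threshold, surface = surface),
            class = "angiogram")
}

#' @export
print.angiogram <- function(x, ...) {
  cat(sprintf(
    "angiogram: %d positions, %d pair(s) rejected (threshold %.3f)%s\n",
    dim(x$decorrelation)[1], nrow(x$rejected_pairs), x$threshold_used,
    if (!is.null(x$vessel))
      sprintf("; largest lumen %.1f um", x$vessel$lumen_diameter_um) else ""))
  invisible(x)
}
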