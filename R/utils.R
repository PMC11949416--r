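`%||%` <- function(a, b) if (is.null(a)) b else a

#' Structured error helper
#' @noRd
mf_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("mfoct_", class), "mfoct_error")))
}

mf_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(paste0("mfoct_", class), "mfoct_warning")))
}

#' Convert magnitude to decibels
#'
#' OCT intensity is displayed and fitted on a log scale. The package
#' convention is amplitude decibels, 20*log10(|A|); zeros are clamped to the
#' smallest representable double to keep the result finite.
#'
#' @param x complex or nonnegative numeric array.
#' @return numeric array of the same shape, in dB.
#' @export
to_db <- function(x) {
  m <- if (is.complex(x)) Mod(x) else x
  20 * log10(pmax(m, .Machine$double.xmin))
}

#' Circularly-symmetric complex Gaussian draws with unit mean square
#' @noRd
complex_speckle <- function(n) {
  complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) / sqrt(2)
}

#' FFT frequencies in cycles per sample (numpy fftfreq ordering)
#' @noRd
fft_freq <- function(n) {
  c(seq(0L, floor(n / 2)), seq(-(ceiling(n / 2) - 1L), -1L)) / n
}

#' Shift a 2D frame by a (possibly fractional) number of pixels
#'
#' Spectral (Fourier) shift with periodic boundary: exact for complex OCT
#' frames and invertible, which is what sub-pixel registration requires.
#'
#' @param frame numeric or complex matrix.
#' @param shift length-2 numeric, (row shift, column shift) in pixels;
#'   positive moves content toward larger indices.
#' @return matrix of the same type and shape.
#' @export
fourier_shift <- function(frame, shift) {
  nr <- nrow(frame); nc <- ncol(frame)
  fr <- fft_freq(nr); fc <- fft_freq(nc)
  ramp <- exp(-2i * pi * (outer(fr * shift[1], rep(1, nc)) +
                          outer(rep(1, nr), fc * shift[2])))
  out <- stats::fft(stats::fft(frame) * ramp, inverse = TRUE) / (nr * nc)
  if (is.complex(frame)) out else Re(out)
}

#' Envelope of a real signal via the analytic signal
#'
#' @param x numeric vector or matrix (columns are independent signals).
#' @return |analytic signal|, same shape as `x`.
#' @export
analytic_envelope <- function(x) {
  if (is.matrix(x)) return(apply(x, 2, analytic_envelope))
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

#' Impose a finite speckle grain (PSF correlation length) on a white
#' complex field
#'
#' Fully developed OCT speckle is band-limited by the system point-spread
#' function: the speckle grain spans roughly the resolution cell, not a
#' single pixel. This multiplies the field's spectrum by a Gaussian whose
#' width corresponds to a spatial grain of `grain_px` pixels per axis,
#' renormalized so the per-voxel variance (and hence the Rayleigh magnitude
#' statistics) is preserved.
#'
#' @param field complex matrix (white circular Gaussian field).
#' @param grain_px length-2 grain size (rows, cols) in pixels; values
#'   <= 1 leave that axis white.
#' @return complex matrix, same shape and per-voxel variance.
#' @export
bandlimit_speckle <- function(field, grain_px = c(1.5, 2)) {
  if (all(grain_px <= 1)) return(field)
  nr <- nrow(field); nc <- ncol(field)
  hr <- if (grain_px[1] > 1) exp(-2 * (pi * grain_px[1] / 2 * fft_freq(nr))^2) else rep(1, nr)
  hc <- if (grain_px[2] > 1) exp(-2 * (pi * grain_px[2] / 2 * fft_freq(nc))^2) else rep(1, nc)
  H <- outer(hr, hc)
  H <- H / sqrt(mean(H^2))  # preserve variance
  stats::fft(stats::fft(field) * H, inverse = TRUE) / (nr * nc)
}

#' Sub-sample peak location by parabolic interpolation
#' @param y numeric vector; @return fractional index of the peak.
#' @noRd
parabolic_peak <- function(y) {
  p <- which.max(y)
  if (p == 1 || p == length(y)) return(as.numeric(p))
  a <- y[p - 1]; b <- y[p]; c <- y[p + 1]
  denom <- a - 2 * b + c
  if (denom == 0) return(as.numeric(p))
  p + 0.5 * (a - c) / denom
}
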