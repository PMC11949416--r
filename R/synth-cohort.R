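# Synthetic cohorts: groups of subjects whose true wave speed, attenuation
# slope and vessel lumen diameter are drawn from configured distributions,
# with matched phantoms for each analysis arm.

#' Configure a synthetic cohort
#'
#' Each group draws per-subject true parameters from normal distributions
#' (mean, SD), truncated at physical bounds by redrawing (speed > 0,
#' diameter > 0, attenuation slope < 0). Defaults carry the group-level
#' parameters of a murine skin-fibrosis study: control wave speed
#' 1.2 +/- 0.2 m/s versus fibrotic 1.6 +/- 0.3 m/s, n = 6 per group.
#'
#' @param groups named list; each element is a list with fields `n` and any
#'   of `wave_speed = c(mean, sd)` (m/s), `octss = c(mean, sd)` (dB/mm),
#'   `lumen_um = c(mean, sd)` (um).
#' @param arms which phantom arms to generate per subject: subset of
#'   `c("oce", "structural", "octa")`.
#' @param axes OCE scan axes per subject (1 or 2; the in vivo protocol scans
#'   lateral-medial and rostral-caudal and averages).
#' @param oce_meta,structural_meta,octa_meta [scan_metadata()] used for each
#'   arm's phantoms; `NULL` selects compact validation-scale defaults.
#' @param phase_snr_db phase SNR of the OCE phantoms (dB).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(groups = list(
                            control = list(n = 6, wave_speed = c(1.2, 0.2)),
                            fibrotic = list(n = 6, wave_speed = c(1.6, 0.3))),
                          arms = "oce", axes = 2L,
                          oce_meta = NULL, structural_meta = NULL,
                          octa_meta = NULL, phase_snr_db = 20) {
  for (g in names(groups)) {
    cfg <- groups[[g]]
    if (is.null(cfg$n) || cfg$n < 1) {
      mf_stop(sprintf("group '%s' must have n >= 1", g), "invalid_config")
    }
    for (m in intersect(names(cfg), c("wave_speed", "octss", "lumen_um"))) {
      if (length(cfg[[m]]) != 2 || cfg[[m]][2] < 0) {
        mf_stop(sprintf("group '%s' metric '%s' must be c(mean, sd >= 0)", g, m),
                "invalid_config")
      }
    }
  }
  structure(list(groups = groups, arms = arms, axes = as.integer(axes),
                 oce_meta = oce_meta %||% oce_meta_default(),
                 structural_meta = structural_meta %||% structural_meta_default(),
                 octa_meta = octa_meta %||% octa_meta_default(),
                 phase_snr_db = phase_snr_db),
            class = "cohort_config")
}

#' Compact validation-scale scan geometries
#'
#' Physics parameters (wavelength, timing, refractive index, pitches) are
#' the instrument values; only the grid extents are reduced so that whole
#' cohorts can be simulated quickly.
#' @rdname cohort_config
#' @export
oce_meta_default <- function() {
  scan_metadata(n_bscans = 61L, n_alines_per_bscan = 1000L,
                n_depth_pixels = 34L, lateral_pixel_size = 5e-5,
                repeats_per_position = 1L)
}

#' @rdname cohort_config
#' @export
structural_meta_default <- function() {
  scan_metadata(n_bscans = 1L, n_alines_per_bscan = 400L,
                n_depth_pixels = 360L, repeats_per_position = 5L)
}

#' @rdname cohort_config
#' @export
octa_meta_default <- function() {
  scan_metadata(n_bscans = 40L, n_alines_per_bscan = 100L,
                n_depth_pixels = 60L, repeats_per_position = 5L,
                lateral_pixel_size = 6.12e-6, slow_pixel_size = 5.56e-6)
}

#' Truncated-normal draw by redraw
#' @noRd
draw_trunc <- function(n, mean, sd, ok) {
  x <- stats::rnorm(n, mean, sd)
  for (i in seq_len(1000)) {
    bad <- !ok(x)
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Draw the per-subject ground truths of a cohort
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; draws are deterministic given (config, seed).
#' @return data.frame with columns `group`, `subject`, `subject_seed` and the
#'   drawn true metrics.
#' @export
draw_cohort_truths <- function(config, seed) {
  withr::with_seed(as.integer(seed), {
    rows <- lapply(names(config$groups), function(g) {
      cfg <- config$groups[[g]]
      n <- cfg$n
      out <- data.frame(group = g, subject = seq_len(n),
                        subject_seed = sample.int(2^31 - 2, n))
      out$wave_speed <- if (!is.null(cfg$wave_speed)) {
        draw_trunc(n, cfg$wave_speed[1], cfg$wave_speed[2], function(x) x > 0)
      } else NA_real_
      out$octss <- if (!is.null(cfg$octss)) {
        draw_trunc(n, cfg$octss[1], cfg$octss[2], function(x) x < 0)
      } else NA_real_
      out$lumen_um <- if (!is.null(cfg$lumen_um)) {
        draw_trunc(n, cfg$lumen_um[1], cfg$lumen_um[2], function(x) x > 0)
      } else NA_real_
      out
    })
    do.call(rbind, rows)
  })
}

#' Generate the phantoms for one cohort subject
#'
#' @param truth_row one row of [draw_cohort_truths()].
#' @param config a [cohort_config()].
#' @return named list of phantoms for the configured arms; the OCE arm is a
#'   list with one `mb_scan` per axis.
#' @export
make_subject_phantoms <- function(truth_row, config) {
  out <- list()
  sseed <- truth_row$subject_seed
  if ("oce" %in% config$arms && is.finite(truth_row$wave_speed)) {
    meta <- config$oce_meta
    tr <- phantom_truth(surface_depth_index = 8L,
                        wave_speed = truth_row$wave_speed)
    tr$phase_noise_sd <- phase_noise_for_snr(tr, meta, config$phase_snr_db)
    axes <- c("lateral-medial", "rostral-caudal")[seq_len(config$axes)]
    out$oce <- lapply(seq_along(axes), function(k) {
      make_oce_phantom(tr, meta, seed = sseed + k, axis_label = axes[k])
    })
  }
  if ("structural" %in% config$arms && is.finite(truth_row$octss)) {
    meta <- config$structural_meta
    tr <- phantom_truth(surface_depth_index = 40L, edj_depth = 60e-6,
                        attenuation_slope = truth_row$octss)
    out$structural <- make_structural_phantom(tr, meta, seed = sseed + 11L)
  }
  if ("octa" %in% config$arms && is.finite(truth_row$lumen_um)) {
    meta <- config$octa_meta
    tr <- phantom_truth(
      surface_depth_index = 12L,
      vessel_set = list(list(
        centerline = cbind(c(1, meta$n_bscans),
                           rep((meta$n_alines_per_bscan + 1) / 2, 2)),
        depth_um = 140, diameter_um = truth_row$lumen_um)))
    out$octa <- make_octa_phantom(tr, meta, seed = sseed + 23L)
  }
  out
}

#' Generate a whole synthetic cohort
#'
#' Materializes truths and phantoms for every subject. For large cohorts
#' prefer [run_pipeline()], which generates and analyses subjects one at a
#' time.
#'
#' @inheritParams draw_cohort_truths
#' @return list with `truths` (data.frame) and `subjects` (list of phantom
#'   lists, in row order of `truths`).
#' @export
make_cohort <- function(config, seed) {
  truths <- draw_cohort_truths(config, seed)
  subjects <- lapply(seq_len(nrow(truths)),
                     function(i) make_subject_phantoms(truths[i, ], config))
  list(truths = truths, subjects = subjects)
}
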