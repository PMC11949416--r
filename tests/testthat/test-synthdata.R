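# Phantom generators: determinism, speckle statistics, phase encoding and
# geometric ground truth.

test_that("generators are pure functions of (truth, meta, seed)", {
  meta <- small_structural_meta(nx = 40L, nz = 120L)
  tr <- phantom_truth(surface_depth_index = 40L, attenuation_slope = -0.5)
  v1 <- make_structural_phantom(tr, meta, seed = 11)
  v2 <- make_structural_phantom(tr, meta, seed = 11)
  v3 <- make_structural_phantom(tr, meta, seed = 12)
  expect_identical(v1$data, v2$data)
  expect_false(identical(v1$data, v3$data))

  om <- small_oce_meta(nx = 21L, nt = 300L, nz = 20L)
  m1 <- make_oce_phantom(oce_truth(meta = om), om, seed = 5)
  m2 <- make_oce_phantom(oce_truth(meta = om), om, seed = 5)
  expect_identical(m1$data, m2$data)

  am <- small_octa_meta(nb = 4L, nx = 50L, nz = 40L)
  a1 <- make_octa_phantom(vessel_truth(85, am), am, seed = 2)
  a2 <- make_octa_phantom(vessel_truth(85, am), am, seed = 2)
  expect_identical(a1$data, a2$data)
})

test_that("structural phantom speckle magnitudes are Rayleigh", {
  meta <- small_structural_meta(nx = 300L, nz = 120L)
  tr <- phantom_truth(surface_depth_index = 30L, attenuation_slope = -0.01,
                      noise_floor_level = 0)
  v <- make_structural_phantom(tr, meta, seed = 21)
  # one depth row just below the surface: constant speckle scale; stride 3
  # decorrelates the grain so the KS test sees independent draws
  z <- 40L
  sig <- tr$signal_level *
    10^(tr$attenuation_slope * (z - 30) * tissue_pitch(meta) * 1e3 / 20)
  a <- Mod(v$data[, 1, z, seq(1, meta$n_alines_per_bscan, by = 3)])
  expect_gt(length(a), 300)
  # |A|^2 / sigma^2 ~ Exp(1) for circular complex Gaussian speckle
  u <- 1 - exp(-(a / sig)^2)
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("ensemble dB decay below the surface matches the imposed slope", {
  meta <- small_structural_meta(nx = 150L, nz = 250L)
  tr <- phantom_truth(surface_depth_index = 30L, attenuation_slope = -0.625,
                      noise_floor_level = 1e-6)
  # ensemble average over repeats x A-lines of the dB profile
  prof <- 0
  nreal <- 25L
  for (s in seq_len(nreal)) {
    v <- make_structural_phantom(tr, meta, seed = 100 + s)
    db <- to_db(v$data[, 1, , ])          # [repeat, depth, lateral]
    prof <- prof + apply(db, 2, mean) / nreal
  }
  z <- 40:220
  x_mm <- z * tissue_pitch(meta) * 1e3
  slope <- stats::coef(stats::lm(prof[z] ~ x_mm))[2]
  expect_equal(unname(slope), -0.625, tolerance = 0.02 / 0.625)
  # near-zero slope gives a flat ensemble profile
  tr0 <- phantom_truth(surface_depth_index = 30L, attenuation_slope = -1e-9,
                       noise_floor_level = 1e-6)
  v0 <- make_structural_phantom(tr0, meta, seed = 7)
  p0 <- apply(to_db(v0$data[, 1, , ]), 2, mean)
  expect_lt(abs(mean(p0[40:80]) - mean(p0[180:220])), 0.5)
})

test_that("structural phantom rejects geometry without room for decay", {
  meta <- small_structural_meta(nx = 20L, nz = 50L)
  tr <- phantom_truth(surface_depth_index = 45L, attenuation_slope = -0.5)
  expect_error(make_structural_phantom(tr, meta, seed = 1),
               class = "mfoct_invalid_geometry")
  expect_error(make_structural_phantom(
    phantom_truth(surface_depth_index = 10L, attenuation_slope = 0.2),
    meta, seed = 1), class = "mfoct_invalid_truth")
})

test_that("OCE phantom encodes the imposed velocity field exactly", {
  om <- small_oce_meta(nx = 31L, nt = 500L, nz = 16L)
  tr <- oce_truth(speed = 1.5, meta = om)
  mb <- make_oce_phantom(tr, om, seed = 3)
  vz_true <- oce_velocity_field(tr, om)
  vz_rec <- phase_to_velocity(phase_difference(mb), om)$vz
  # dphi between A-lines k,k+1 encodes vz at A-line k+1
  err <- max(abs(vz_rec[, , 8] - vz_true[, -1]))
  expect_lt(err, 1e-12)
})

test_that("OCE arrival-time delay equals distance over speed", {
  om <- small_oce_meta(nx = 71L, nt = 1000L, nz = 16L, pitch = 1e-4)
  tr <- oce_truth(speed = 1.5, meta = om)
  vz <- oce_velocity_field(tr, om)
  x0 <- 36L
  arrival_of <- function(row) {
    e <- analytic_envelope(vz[row, ])
    p <- which.max(e); th <- e[p] / 2
    l <- p; while (l > 1 && e[l - 1] >= th) l <- l - 1
    r <- p; while (r < length(e) && e[r + 1] >= th) r <- r + 1
    w <- e[l:r]^2
    sum((l:r) * w) / sum(w) * om$temporal_resolution
  }
  # two positions 3.0 mm apart on the same side of the excitation
  d1 <- arrival_of(x0 + 5)   # 0.5 mm
  d2 <- arrival_of(x0 + 35)  # 3.5 mm
  expect_equal(d2 - d1, 3.0e-3 / 1.5, tolerance = 0.02)
})

test_that("zero wave amplitude yields identically zero phase differences", {
  om <- small_oce_meta(nx = 15L, nt = 200L, nz = 12L)
  tr <- oce_truth(meta = om)
  tr$wave_amplitude <- 0
  mb <- make_oce_phantom(tr, om, seed = 9)
  expect_lt(max(abs(phase_difference(mb))), 1e-12)
})

test_that("imposed vz of 11.44 mm/s produces a pi/2 phase difference", {
  om <- small_oce_meta(nx = 5L, nt = 10L, nz = 6L)
  tr <- oce_truth(meta = om)
  # invert the Doppler relation at lambda0 = 1300 nm, n = 1.42, dt = 10 us
  vz_target <- pi / 2 * om$central_wavelength /
    (4 * pi * om$refractive_index * om$temporal_resolution)
  expect_equal(vz_target, 11.44e-3, tolerance = 1e-3)
  dphi_expect <- 4 * pi * om$refractive_index * om$temporal_resolution *
    vz_target / om$central_wavelength
  expect_equal(dphi_expect, pi / 2, tolerance = 1e-12)
})

test_that("aliasing amplitudes are rejected unless flagged", {
  om <- small_oce_meta(nx = 15L, nt = 200L, nz = 12L)
  tr <- oce_truth(meta = om)
  tr$wave_amplitude <- 25e-3   # above the ~22.9 mm/s ceiling
  expect_error(make_oce_phantom(tr, om, seed = 1),
               class = "mfoct_aliasing_configuration")
  tr$allow_aliasing <- TRUE
  expect_s3_class(make_oce_phantom(tr, om, seed = 1), "mb_scan")
})

test_that("OCTA phantom: static voxels repeat, vessel voxels decorrelate", {
  am <- small_octa_meta(nb = 3L, nx = 60L, nz = 50L)
  # no vessels, no shifts, no detection noise: repeats identical
  tr0 <- phantom_truth(surface_depth_index = 12L, noise_floor_level = 0)
  v0 <- make_octa_phantom(tr0, am, seed = 4)
  expect_equal(v0$data[1, 2, , ], v0$data[3, 2, , ], tolerance = 1e-12)

  # one vessel: inter-repeat correlation inside far below outside
  tr1 <- vessel_truth(8 * am$lateral_pixel_size * 1e6, meta = am,
                      bulk_shifts = NULL)
  v1 <- make_octa_phantom(tr1, am, seed = 4)
  mask <- vessel_mask_slice(tr1, am, 2)
  a <- Mod(v1$data[1, 2, , ]); b <- Mod(v1$data[2, 2, , ])
  cm <- correlation_map(list(a, b), kernel = c(5L, 5L))$correlation
  inner <- EBImage::erode(EBImage::Image(mask * 1),
                          EBImage::makeBrush(3, "box")) > 0
  below <- row(mask) > 20 & !mask
  gap <- mean(cm[below]) - mean(cm[inner])
  expect_gte(gap, 0.5)
})

test_that("bulk shift appears at the expected cross-correlation lag", {
  am <- small_octa_meta(nb = 1L, nx = 64L, nz = 48L)
  tr <- phantom_truth(surface_depth_index = 10L,
                      bulk_shifts = rbind(c(0, 0), c(0, 3), c(0, 0),
                                          c(0, 0), c(0, 0)))
  v <- make_octa_phantom(tr, am, seed = 6)
  reg <- register_pair(v$data[1, 1, , ], v$data[2, 1, , ], upsample = 1L)
  expect_equal(unname(reg$shift), c(0, 3))
})

test_that("vessel voxel volume matches the analytic tube volume", {
  am <- small_octa_meta(nb = 30L, nx = 80L, nz = 60L)
  d_um <- 120
  tr <- vessel_truth(d_um, meta = am, bulk_shifts = NULL)
  vox <- sum(vapply(seq_len(am$n_bscans),
                    function(b) sum(vessel_mask_slice(tr, am, b)),
                    integer(1)))
  dz <- tissue_pitch(am) * 1e6
  dx <- am$lateral_pixel_size * 1e6
  dy <- am$slow_pixel_size * 1e6
  v_meas <- vox * dz * dx * dy
  len <- am$n_bscans * dy
  v_true <- pi * (d_um / 2)^2 * len
  shell <- pi * d_um * len * max(dz, dx)   # one-voxel shell around the tube
  expect_lt(abs(v_meas - v_true), shell)
})

test_that("vessels outside the volume raise a geometry error", {
  am <- small_octa_meta(nb = 4L, nx = 40L, nz = 30L)
  tr <- phantom_truth(surface_depth_index = 10L,
                      vessel_set = list(list(
                        centerline = cbind(c(1, 4), c(20, 20)),
                        depth_um = 200, diameter_um = 100)))
  expect_error(make_octa_phantom(tr, am, seed = 1),
               class = "mfoct_invalid_geometry")
})

test_that("cohort draws respect configuration and determinism", {
  cfg <- cohort_config(groups = list(
    control = list(n = 6, wave_speed = c(1.2, 0.2)),
    stiff = list(n = 4, wave_speed = c(1.6, 0))))
  t1 <- draw_cohort_truths(cfg, seed = 31)
  t2 <- draw_cohort_truths(cfg, seed = 31)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 10)
  # SD = 0: all subjects share the configured mean exactly
  expect_true(all(t1$wave_speed[t1$group == "stiff"] == 1.6))
  expect_true(all(t1$wave_speed > 0))
  # distributional check: mean of many draws within 3 SE
  big <- cohort_config(groups = list(control = list(n = 200,
                                                    wave_speed = c(1.2, 0.2))))
  tb <- draw_cohort_truths(big, seed = 77)
  se <- 0.2 / sqrt(200)
  expect_lt(abs(mean(tb$wave_speed) - 1.2), 3 * se)
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(groups = list(g = list(n = 0))),
               class = "mfoct_invalid_config")
  expect_error(cohort_config(groups = list(g = list(n = 3,
                                                    wave_speed = c(1, -1)))),
               class = "mfoct_invalid_config")
})

test_that("containers round-trip phantoms through disk", {
  om <- small_oce_meta(nx = 9L, nt = 50L, nz = 14L)
  mb <- make_oce_phantom(oce_truth(meta = om), om, seed = 2)
  path <- tempfile(fileext = ".rds")
  write_oct_container(mb, path)
  back <- read_oct_container(path)
  expect_identical(back$data, mb$data)
  expect_identical(back$axis_label, mb$axis_label)
  unlink(path)
  expect_error(write_oct_container(list(1), tempfile()),
               class = "mfoct_invalid_container")
})
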