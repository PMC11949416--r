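# Angiography arm: registration, correlation mapping, SNR masking, pair
# rejection, stripe filtering, projection, lumen measurement.

speckle_frame <- function(nz = 60L, nx = 100L, seed = 3) {
  set.seed(seed)
  bandlimit_speckle(matrix(complex(real = stats::rnorm(nz * nx),
                                   imaginary = stats::rnorm(nz * nx)),
                           nz, nx), c(1.5, 2))
}

test_that("register_pair recovers integer and sub-pixel shifts", {
  base <- speckle_frame()
  expect_equal(unname(register_pair(base, base)$shift), c(0, 0))
  r1 <- register_pair(base, fourier_shift(base, c(3, -2)), upsample = 1L)
  expect_equal(unname(r1$shift), c(3, -2))
  r2 <- register_pair(base, fourier_shift(base, c(0.3, 0)), upsample = 20L)
  expect_lt(abs(r2$shift[1] - 0.3), 0.1)
  expect_lt(abs(r2$shift[2]), 0.1)
  # registered frame is realigned with the reference
  expect_lt(mean(Mod(r2$registered - base)) / mean(Mod(base)), 0.1)
  expect_error(register_pair(matrix(0i, 4, 4), matrix(0i, 4, 4)),
               class = "mfoct_registration_undefined")
  expect_error(register_pair(base, base[, 1:50]),
               class = "mfoct_invalid_input")
})

test_that("correlation_map separates static and independent content", {
  a <- Mod(speckle_frame(seed = 11))
  expect_true(all(abs(correlation_map(list(a, a))$correlation - 1) < 1e-6))
  # independent white noise: |ZNCC| small at a 5x5 kernel
  set.seed(12)
  n1 <- matrix(abs(stats::rnorm(60 * 100)), 60, 100)
  n2 <- matrix(abs(stats::rnorm(60 * 100)), 60, 100)
  cm <- correlation_map(list(n1, n2))
  expect_lte(mean(abs(cm$correlation)), 0.2)
  expect_error(correlation_map(list(n1, n2), kernel = c(4L, 5L)),
               class = "mfoct_invalid_kernel")
  expect_error(correlation_map(list(n1, n2), kernel = c(61L, 61L)),
               class = "mfoct_invalid_kernel")
  expect_error(correlation_map(list(n1)), class = "mfoct_invalid_input")
})

test_that("snr_correct inverts correlation and masks sub-noise pixels", {
  corr <- matrix(1, 10, 10)
  intensity <- matrix(0, 10, 10)
  np <- list(mean = -60, sd = 1)
  expect_true(all(snr_correct(corr, intensity, np) == 0))
  # a sub-noise pixel with zero correlation is masked, not called flow
  corr[5, 5] <- 0
  intensity[5, 5] <- -60
  dec <- snr_correct(corr, intensity, np)
  expect_equal(dec[5, 5], 0)
  intensity[5, 5] <- 0
  expect_equal(snr_correct(corr, intensity, np)[5, 5], 1)
  expect_error(snr_correct(corr, intensity, list(mean = NULL, sd = 1)),
               class = "mfoct_noise_estimation")
})

test_that("reject_pairs applies the mean-minus-SD threshold", {
  gc <- c(0.90, 0.92, 0.88, 0.50)
  r <- reject_pairs(gc)
  expect_equal(r$threshold, mean(gc) - stats::sd(gc), tolerance = 1e-12)
  expect_equal(r$threshold, 0.599, tolerance = 1e-3)
  expect_identical(r$keep, c(TRUE, TRUE, TRUE, FALSE))
  # all equal: nothing strictly below value - 0
  expect_true(all(reject_pairs(rep(0.8, 5))$keep))
  # wide two-pair case: threshold below both
  r2 <- reject_pairs(c(0.9, 0.1))
  expect_lt(r2$threshold, 0)
  expect_true(all(r2$keep))
  # scale invariance of the keep mask
  k <- 3.7
  expect_identical(reject_pairs(k * gc)$keep, r$keep)
  expect_equal(reject_pairs(k * gc)$threshold, k * r$threshold,
               tolerance = 1e-12)
})

test_that("stripe_filter removes slow-axis stripes and little else", {
  # smooth stripe-free image: gentle gradient plus a vessel along the slow
  # axis (no genuine row-offset content)
  img <- outer(rep(1, 40), 0.1 + 0.001 * seq_len(100))
  img[, 45:55] <- img[, 45:55] + 0.8
  f <- stripe_filter(img)
  expect_lt(sqrt(mean((f - img)^2)) / sqrt(mean(img^2)), 0.01)
  # constant-offset rows on 5% of positions: excess largely removed
  striped <- img
  striped[c(7, 31), ] <- striped[c(7, 31), ] + 1
  fs <- stripe_filter(striped)
  excess_before <- mean(striped[7, ] - img[7, ])
  excess_after <- mean(fs[7, ] - img[7, ])
  expect_lt(excess_after / excess_before, 0.2)
  # pure stripes collapse (only the grand mean survives)
  pure <- matrix(0, 40, 100)
  pure[3, ] <- 1
  expect_lt(sqrt(mean(stripe_filter(pure)^2)) / sqrt(mean(pure^2)), 0.2)
})

test_that("mip_enface projects depth maxima below the surface", {
  vol <- array(0, dim = c(4, 20, 6))
  vol[2, 12, 3] <- 0.7
  m <- mip_enface(vol, surface = 5L)
  expect_equal(m[2, 3], 0.7)
  expect_equal(sum(m), 0.7)
  expect_true(all(mip_enface(array(0, dim = c(3, 10, 4)), 2L) == 0))
  # voxels above the surface are excluded
  vol[2, 3, 3] <- 5
  expect_equal(mip_enface(vol, surface = 5L)[2, 3], 0.7)
})

test_that("measure_lumen picks the largest vessel and needs a vessel", {
  mip <- matrix(0, 60, 80)
  mip[10:50, 20:24] <- 1   # 5 px wide
  mip[10:50, 60:69] <- 1   # 10 px wide
  m <- measure_lumen(mip, pitches = c(6e-6, 6e-6))
  expect_equal(m$lumen_diameter_um, 10 * 6, tolerance = 6)
  expect_gt(m$measurement_location[2], 55 * 6e-6)
  expect_error(measure_lumen(matrix(0, 30, 30), pitches = c(6e-6, 6e-6)),
               class = "mfoct_no_vessel_found")
})

test_that("static phantoms stay dark under bulk motion", {
  am <- small_octa_meta(nb = 6L, nx = 80L, nz = 60L)
  tr <- phantom_truth(surface_depth_index = 12L,
                      bulk_shifts = rbind(c(0, 0), c(1, -3), c(3, 2),
                                          c(-2, 1), c(0.5, -0.5)))
  v <- make_octa_phantom(tr, am, seed = 7)
  ang <- suppressWarnings(octa_pipeline(v, noise_rows = 8L, measure = FALSE))
  below <- ang$decorrelation[, 15:55, ]
  expect_lte(mean(below > 0.3), 0.01)
})

test_that("octa_pipeline segments the vessel and measures its lumen", {
  am <- small_octa_meta()
  tr <- vessel_truth(105, meta = am)
  v <- make_octa_phantom(tr, am, seed = 31)
  ang <- suppressWarnings(octa_pipeline(v, noise_rows = 8L))
  expect_lt(abs(ang$vessel$lumen_diameter_um - 105),
            am$lateral_pixel_size * 1e6 + 1e-9)
  # en-face footprint overlap with the generator truth
  fp <- vessel_footprint(tr, am)
  mp <- pmin(pmax(ang$mip_filtered, 0), 1)
  mask <- mp > EBImage::otsu(EBImage::Image(mp))
  dice <- 2 * sum(mask & fp) / (sum(mask) + sum(fp))
  expect_gte(dice, 0.7)
})

test_that("breathing-corrupted positions are rejected and excluded", {
  am <- small_octa_meta(nb = 20L, nx = 60L, nz = 50L)
  tr <- phantom_truth(
    surface_depth_index = 12L,
    vessel_set = list(list(centerline = cbind(c(1, 20), c(30.5, 30.5)),
                           depth_um = 140, diameter_um = 100)),
    breathing = list(amplitude_px = 25, frequency_hz = 2,
                     positions = c(5L, 13L)))
  v <- make_octa_phantom(tr, am, seed = 41)
  ang <- suppressWarnings(octa_pipeline(v, noise_rows = 8L, measure = FALSE))
  # both corrupted positions must surface in the rejection log; rigid
  # registration absorbs part of the motion, so individual mildly-moved
  # pairs may legitimately survive
  expect_true(all(c(5L, 13L) %in% ang$rejected_pairs[, "position"]))
  disp <- breathing_displacements(tr, am)
  expect_gt(max(abs(disp[5, ])), 1)
  expect_true(all(disp[-c(5, 13), ] == 0))
})
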