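# mfoct — multifunctional OCT analysis of skin

`mfoct` is an R package for quantitative analysis of complex-valued
swept-source optical coherence tomography (OCT) scans of skin, built around
the three measurements used to track dermal fibrosis in vivo:

* **OCTSS** — the OCT signal slope: per-A-line least-squares decay of the
  dB intensity over the dermis (dB/mm), with intensity-based tracking of
  the tissue surface, the noise floor and the epidermis–dermis junction
  (EDJ), falling back to a configured dermis depth where fibrosis has
  erased the junction.
* **OCE** — optical coherence elastography: the inter-A-line phase
  difference of M-B-mode scans is converted to axial particle velocity by
  `vz = Δφ·λ₀/(4π·n·Δt)` (λ₀ = 1300 nm, n = 1.42, Δt = 10 µs), band-passed
  at the 1 kHz excitation, averaged over 170 µm below the surface into a
  space–time map, and the surface-wave speed is estimated by robust
  (bisquare-IRLS) regression of per-position arrival times — stiffer skin
  carries the wave faster.
* **cm-OCA** — correlation-mapping OCT angiography on repeated B-scans:
  DFT sub-pixel registration of bulk motion, windowed zero-mean normalised
  cross-correlation between consecutive repeats, SNR-aware noise masking,
  mean-minus-SD rejection of motion-corrupted pairs, breathing-stripe
  removal in the spectral domain, en-face maximum-intensity projection and
  automatic lumen-diameter measurement of the largest vessel.

Because raw acquisitions of this kind are not publicly deposited, the
package includes a synthetic phantom generator (`make_structural_phantom`,
`make_oce_phantom`, `make_octa_phantom`, `make_cohort`) that emulates the
acquisition physics — fully developed speckle with a finite grain, layered
exponential attenuation, a travelling 1 kHz burst encoded in phase,
decorrelating vessel tubes, sub-pixel bulk motion and breathing stripes —
with known ground truth, so the whole pipeline is validated by parameter
recovery. A cohort layer (`run_pipeline`) aggregates per-sample metrics
into group summaries (mean ± SD, median, 5th/95th percentiles) and
pooled-variance t-tests.

## Worked example

Simulate an M-B-mode scan of skin carrying a 1.5 m/s surface wave at
20 dB phase SNR, and estimate the speed:

```r
library(mfoct)

meta <- scan_metadata(n_bscans = 61, n_alines_per_bscan = 1000,
                      n_depth_pixels = 34, lateral_pixel_size = 5e-5,
                      repeats_per_position = 1)
truth <- phantom_truth(surface_depth_index = 8, wave_speed = 1.5)
truth$phase_noise_sd <- phase_noise_for_snr(truth, meta, 20)

mb  <- make_oce_phantom(truth, meta, seed = 1)
fit <- oce_pipeline(mb)
fit
#> wave speed: 1.498 m/s (left 1.498, right 1.498; R2 1.000, inliers 86%)
```

The estimate recovers the ground-truth 1.5 m/s to 0.2%; `per_side_speeds`
are the independent fits left and right of the excitation point, and
`inlier_fraction` is the share of lateral positions keeping full bisquare
weight. The same phantom-to-estimate loop runs for the structural arm
(`make_structural_phantom` → `octss_pipeline`) and the angiography arm
(`make_octa_phantom` → `octa_pipeline`), and `run_pipeline(cohort_config(),
seed)` carries whole synthetic cohorts through to group comparisons:

```r
res <- run_pipeline(cohort_config(groups = list(
         control  = list(n = 6, wave_speed = c(1.2, 0.2)),
         fibrotic = list(n = 6, wave_speed = c(1.6, 0.3)))), seed = 42)
res$comparisons[, c("group_a", "group_b", "t_statistic", "p_value")]
```

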