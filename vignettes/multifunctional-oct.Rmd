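---
title: "Multifunctional OCT analysis of skin: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifunctional OCT analysis of skin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfoct)
```

## What this package computes

`mfoct` analyses complex-valued swept-source OCT acquisitions of skin with
three arms that together characterise fibrotic change:

* **OCTSS (structural)** — the OCT signal slope: the linear decay rate of
  the depth-resolved log-intensity over the dermis, in dB/mm. Fibrosis
  changes dermal scattering and hence this slope.
* **OCE (elastography)** — the propagation speed of a 1 kHz quasi-harmonic
  surface wave launched by an air-coupled ultrasound push. Stiffer
  (fibrotic) skin carries the wave faster; speeds of 1–2.5 m/s span the
  healthy-to-fibrotic range in mouse dorsal skin.
* **cm-OCA (angiography)** — correlation-mapping angiography: moving blood
  decorrelates speckle between repeated B-scans while static dermis stays
  correlated. The en-face projection yields vessel maps, quantified here by
  the lumen diameter of the largest vessel.

Because raw in vivo data of this kind are not publicly deposited, the
package ships a synthetic phantom generator that emulates the acquisition
physics with known ground truth, so every stage is validated by parameter
recovery rather than by comparison to an inaccessible recording.

## The measurement models

### Phase-sensitive particle velocity

Two A-lines acquired `dt` apart at the same beam position differ in phase
by `dphi = 4*pi*n*dt*vz / lambda0` when the scatterers move axially at
velocity `vz`; inverting gives

```
vz = dphi * lambda0 / (4 * pi * n * dt)
```

with `lambda0 = 1300 nm`, `n = 1.42`, `dt = 10 us` at the 100 kHz sweep
rate. A quarter-turn phase shift (`dphi = pi/2`) therefore corresponds to
11.44 mm/s, and the principal-value wrap at `|dphi| = pi` caps measurable
velocities at about 22.9 mm/s. The package performs no phase unwrapping:
amplitudes that respect this ceiling are the supported regime, and the
generator refuses aliasing configurations unless explicitly flagged for
aliasing tests.

### Wave-speed estimation

The M-B-mode protocol records 1000 A-lines (10 ms) at each lateral
position, with the excitation synchronized to the frame trigger, so the
sequence of positions samples one repeatable wave at 100 kHz. The chain is:

1. `phase_difference` / `phase_to_velocity` — Doppler conversion above;
2. `bandpass_excitation` — 4th-order Butterworth, `f0 ± 200 Hz`, run
   forward–backward (zero phase). Physiological motion (breathing ≈ 2 Hz)
   falls ≥ 40 dB below the passband;
3. `build_st_map` — average the filtered velocity over a 170 µm depth
   window below the detected surface, per lateral position, producing a
   position × time map with a V-shaped wavefront;
4. `fit_wave_speed` — per lateral position the arrival time is the energy
   centroid of the half-maximum region of the envelope (magnitude of the
   analytic signal); per side of the excitation, arrival time is regressed
   on distance with iteratively reweighted least squares (bisquare
   weights, via `MASS::rlm`, ≤ 50 iterations); speed = 1/slope, sides
   averaged, sides with weighted R² < 0.5 dropped with a warning.

Design choices worth recording:

* **Time-of-flight versus image-rotation slope.** The slope of the
  space–time map can be extracted either from per-position arrival times
  or from a global 2D transform (e.g. Radon). Arrival-time regression was
  chosen: it pairs naturally with residual-weighted robust fitting, keeps
  each lateral position an independent observation (so corrupted positions
  are downweighted individually), and needs no angular discretisation.
* **Envelope centroid, not envelope peak.** The raw envelope peak locks
  onto carrier maxima and quantises arrival times; the energy centroid of
  the contiguous half-maximum region varies smoothly with sub-sample
  delays. On noiseless phantoms this reduces the speed error from ≈ 2% to
  < 0.2%.
* **Filter padding.** The narrow passband has an impulse response of
  several milliseconds; `filtfilt` applied to the bare trace lets edge
  transients leak inward and bias arrival times by ≈ 1%. Traces are
  padded with their edge values (constant extension) before filtering and
  cropped after, which restores shift invariance for transient signals
  without introducing the broadband step of a hard zero pad.
* **Filtering and depth averaging commute.** Both are linear, so the
  package averages the depth window first and filters once per position;
  the result is identical to filtering every depth and then averaging, at
  a fraction of the cost.
* **Exclusion radius.** Positions within 0.3 mm of the excitation (the
  transducer spot size) are excluded from the fit: the near field is not a
  propagating plane wave.
* **Two axes.** The in vivo protocol scans lateral–medial and
  rostral–caudal lines and averages the two speeds (`average_axes`);
  per-axis measurement error (< 1%) is far below the between-animal spread,
  so cohort simulations may use one axis without changing group statistics.

### OCT signal slope

The dB image (`20*log10 |A|`; the dB convention is a package decision, the
slope is invariant to the overall scale) of the repeat-averaged central
B-scan is segmented by intensity thresholding: air-noise statistics come
from the topmost rows, the surface is the first median-filtered crossing of
noise mean + 4 SD (laterally smoothed with a running median of 15), and the
noise floor is the deepest row whose laterally averaged intensity stays
above noise mean + 3 SD. The epidermis–dermis junction (EDJ) is a thin dark
band searched 20–120 µm below the surface; a dip qualifies only with ≥ 2 dB
prominence on ≥ 50% of A-lines, because fibrotic skin genuinely loses the
junction and absence must remain a valid outcome. When the EDJ is absent
the dermis start falls back to a configured depth (default 60 µm, playing
the role of the cohort-average dermis depth). In both cases the fit starts
two pixels below the junction band so the dark band itself does not lever
the fit. Per A-line, ordinary least squares of dB against physical tissue
depth (axial pitch in air divided by `n = 1.42`) runs from the dermis start
to the noise floor (≥ 20 samples enforced), and the OCTSS is the mean of
the per-A-line slopes.

A note on magnitudes: slopes near −0.05 dB/mm are far smaller than typical
raw skin attenuation; the package reports honest dB per geometric tissue
millimetre and makes no attempt to match any particular absolute
convention. Recovery tests therefore check the generator's imposed slope,
which is exact by construction.

### Correlation-mapping angiography

Per B-scan position, the five repeats are registered to the first by
DFT-based sub-pixel registration (`register_pair`): the integer
cross-correlation peak of the magnitudes is refined to 1/20 px with a
locally upsampled matrix-multiply DFT, and the complex frame is resampled
by a spectral shift. Consecutive registered pairs (4 pairs from 5 repeats —
the minimal reading of pair averaging, at half the cost of all
combinations) are compared by zero-mean normalised cross-correlation in a
5 × 5 window (box statistics via FFT filtering). Global per-pair
correlations, averaged over tissue rows only, are pooled across the whole
volume, and pairs below mean − sample SD (n − 1; the threshold is sensitive
to this convention, hence it is recorded) are rejected; positions losing
all pairs are flagged and excluded downstream. The kept pairs' correlation
maps are averaged, converted to decorrelation (1 − r, clamped to [0, 1]),
and masked wherever the intensity sits within 3 noise SDs of the air noise
level: below the sensitivity floor decorrelation is noise, not flow.
A 3-position running mean along the slow axis then precedes the
maximum-intensity projection: the depth maximum would otherwise ride the
upper tail of the ZNCC noise and inflate vessel halos in proportion to the
vessel's depth extent. Breathing stripes — whole corrupted B-scan
positions, i.e. energy at near-zero fast-axis frequency — are removed by
zeroing spectral coefficients with |fast-axis frequency| < 1 bin at all
nonzero slow-axis frequencies (DC preserved).

The lumen of the largest vessel is measured deterministically (replacing
the manual annotation a human reader would do in a viewer): Otsu
binarisation, largest connected component, centerline from cross-slice
centroids along the component's principal axis (smoothed, because centroid
noise tilts the local normal and an oblique cut overestimates width by
1/cos θ), and the diameter is the maximum over centerline points of the
full width at half maximum of the decorrelation profile along the local
normal, measured above the local background pedestal and averaged over ±2
neighbouring centerline points.

### Cohort statistics

Group summaries report mean, sample SD, median and the 5th/95th
percentiles (linear interpolation), the whisker convention of the study
design. Comparisons use the two-sided pooled-variance Student t-test
(`stats::t.test(var.equal = TRUE)`); Welch would also be defensible, but
pooled variance is the recorded choice and the degenerate zero-variance
equal-mean case returns t = 0, p = 1 by convention. Pearson correlations
come from `stats::cor.test`. No multiple-testing correction is applied —
pairwise p-values are reported raw.

## The phantom generator

`make_structural_phantom`, `make_oce_phantom`, `make_octa_phantom` and
`make_cohort` are pure functions of (truth, metadata, seed).

* **Speckle** is fully developed: circularly symmetric complex Gaussian
  per voxel, band-limited to a configurable grain (default 1.5 px axial ×
  2 px lateral) that stands in for the point-spread function. Band-limiting
  preserves the per-voxel Rayleigh magnitude statistics and is what gives
  sub-pixel registration something to lock onto — per-voxel white speckle
  has no sub-pixel structure.
* **Attenuation** scales the speckle amplitude as
  `10^(slope_dB_per_mm * depth_mm / 20)` below a configurable surface
  profile, so the ensemble dB A-line decays at exactly the ground-truth
  slope. The EDJ is a 2-pixel band of reduced amplitude. Detection noise is
  additive complex Gaussian at a configurable floor.
* **The surface wave** is a square-windowed sinusoidal burst (default 5
  cycles at 1 kHz — the pulse count is unreported for the real drive and
  left configurable) radiating from the scan centre with geometric decay
  `sqrt(r_min / r)`; the decay law is a nuisance parameter the estimator
  must not depend on. The wave modulates voxel phase through the cumulative
  displacement, so the Doppler chain recovers the imposed velocity field
  exactly at zero noise. Phase SNR is defined as peak inter-A-line phase
  shift over the SD of the inter-A-line phase-difference noise.
* **Vessels** are tubes (centerline polyline, depth, lumen diameter) whose
  voxels redraw independent speckle every repeat — full decorrelation, the
  limiting behaviour of fast flow. Bulk motion displaces whole repeats by
  sub-pixel spectral shifts; breathing corrupts configured positions with a
  large depth-dependent (shearing) lateral displacement sampled at the
  instrument's 10 ms frame cadence, which rigid registration cannot undo —
  that is what makes stripes.
* **Cohorts** draw per-subject true wave speed, attenuation slope and lumen
  diameter from configured normal distributions, truncated at physical
  bounds by redrawing (which preserves the configured mean to first order
  at these coefficient-of-variation levels).

What the phantoms deliberately do not model: beam propagation or photon
transport, heartbeat, wave dispersion in layered media, partial-volume
flow, or vessel networks. Passing recovery tests therefore demonstrates
the correctness of the estimators under the stated acquisition model, not
robustness to every in vivo nuisance.

## Validation scales and numerical choices

Simulations use reduced grids — e.g. 41–61 lateral positions for M-B
scans, 30–34 depth pixels with the surface at pixel 8, 40 × 100 × 60
angiography volumes — while keeping every physical parameter (wavelength,
timing, pitches, refractive index, speeds, SNR, lumen diameters in
micrometres) at instrument values. These sizes are the package's
validation choices; the estimators themselves are size-agnostic.

Numerical points a maintainer should know:

* The 800–1200 Hz Butterworth at 100 kHz sampling is narrow: its pole
  cluster amplifies last-bit input perturbations by many orders of
  magnitude. Estimates are unaffected (arrival statistics average over
  hundreds of samples), but filtered traces are reproducible only to the
  filter's conditioning, not to machine epsilon — tests compare them at
  relative, not absolute, tolerances.
* `fit_wave_speed` falls back to ordinary least squares when residuals are
  at floating-point zero (a perfect line breaks the IRLS scale estimate)
  and guards against non-positive slopes (infinite or acausal speeds) with
  an explicit error.
* Registration, spectral shifts and the stripe filter all assume periodic
  boundaries (FFT); phantom bulk shifts are likewise periodic, so
  registration inverts them exactly.
* Surface detection needs a genuine air gap above the tissue; the number
  of guaranteed-air rows is a parameter (`noise_rows`) because scaled-down
  phantoms place the surface higher than a full 500-pixel A-line would.

## Known limitations

* Wave speed is reported as-is; no conversion to shear or Young's modulus
  and no dispersion analysis is attempted.
* The OCTSS is a single linear fit per A-line, not a depth-resolved
  attenuation-coefficient map.
* Lumen measurement assumes one dominant, roughly tubular vessel; no
  network metrics (density, tortuosity, branching) are computed.
* The mean − SD pair-rejection threshold is relative: in a clean volume it
  still trims the low tail (~16% of pairs), which is faithful to the rule
  rather than a defect of the implementation.
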