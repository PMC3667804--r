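---
title: "Seed-based LFF connectivity: model, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-based LFF connectivity: model, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

In resting-state BOLD fMRI, spatially remote regions exhibit synchronized
low-frequency fluctuations (LFF, below 0.08 Hz), and the strength of that
synchronization — functional connectivity — is a sensitive, non-invasive
index of network integrity. `lffconn` implements a classical seed-based
analysis of this signal for a longitudinal rodent design: bilateral
coupling between homotopic primary somatosensory cortex (SI) and
hippocampus (Hp) is measured before an intervention and on recovery days
1, 3 and 9, where the interesting phenomenology is a transient loss of
right-hemisphere coupling on days 1 and 3 with restoration by day 9,
paralleling a transient spatial-memory deficit in a Y-maze task.

Because no raw scans are available for that design, the package pairs the
analysis pipeline with a synthetic 4D BOLD generator that emulates the
study conditions with known ground truth. Everything the pipeline
computes on real NIfTI data it computes identically on generated data.

## The analysis model

For each rat and session, a 4D run `(x, y, z, t)` is processed as:

1. **Dummy-scan removal** — the leading steady-state volumes (5 by
   default) are discarded, leaving 120 volumes at TR 2 s.
2. **Spatial smoothing** — separable Gaussian, FWHM 7.8 mm, applied at
   10x voxel scale (see "Voxel scaling" below), i.e. about 1.5 in-plane
   voxels.
3. **Linear detrending** — the least-squares line is removed per voxel,
   eliminating slow scanner drift.
4. **Ideal low-pass at 0.08 Hz** — discrete Fourier coefficients above
   the cutoff are zeroed; the filter is zero-phase, linear and idempotent
   (an orthogonal projection).

A seed reference is the mean timecourse of a 2x2-pixel, single-slice ROI
at the left-SI atlas point (-4.2, -2.2, -0.2) mm or the left-Hp point
(-4.8, -2.4, -0.4) mm. The map statistic is the lag-0 Pearson correlation
of every voxel with the reference.

### Significance with effective degrees of freedom

Low-pass filtering leaves neighbouring samples strongly dependent, so the
null distribution of `r` must use the *effective* degrees of freedom. The
package uses the bandwidth-ratio rule

    df = N * 2 * f_c * TR - 2 = 120 * 2 * 0.08 * 2 - 2 = 36.4

and thresholds at the correlation whose `t = r * sqrt(df / (1 - r^2))`
attains the nominal one-sided tail probability (default `P < 2.5e-5`,
giving `r >= 0.606` at the study settings). One-sided thresholds are the
default because the analysis counts *synchronized* (positively
correlated) voxels; a two-sided variant is available.

For the ideal filter this rule can be checked exactly: the filter retains
the DC bin plus 19 complex bins (`k/240 <= 0.08` Hz), i.e. 39 real
spectral coordinates; mean removal in the correlation eliminates DC, so
the exact null of `r` is a t distribution with 37 df. The bandwidth rule
gives 36.4 — close enough that Monte-Carlo calibration of the one-sided
exceedance (which the test suite performs at 1e5 pairs for p = 0.01 and
0.001 and 1e6 pairs for p = 2.5e-5, via `null_calibration()`) stays
within 3 binomial standard errors of nominal, with a known mild
conservative bias of about -1.4 SE at p = 0.01. We keep the bandwidth
formula because it is the convention this analysis family uses and the
discrepancy is far below the resolution of any downstream count.

### Counting and normalization

Supra-threshold voxels (`r >= r_critical`, ties significant by
definition — deterministic and stated) are counted inside anatomical
region masks, per hemisphere and in total. Counts are normalized per rat
by the same region's preoperative count, so the preoperative column is
identically 1.00 and a day-1 value of 0.02 means 2% of the baseline
extent survived. Undefined normalizations (preoperative count 0) are
flagged `NA` and excluded from cohort means.

### Group maps

Group-level inference applies Fisher's z to each rat's map and a
voxel-wise one-sample t test of z against 0 across rats (one-sided,
uncorrected, default `P < 0.001`). A one-sample test of raw correlations
"against 1" is not computable — r = 1 is the boundary of the parameter
space, where z diverges — so the test is performed on the z scale against
0 and that decision is recorded in the output metadata. Degenerate voxels
(zero variance across rats with non-zero mean) are flagged undefined
rather than given infinite statistics; all-zero voxels carry no evidence
and report `t = 0, p = 1`.

## The synthetic cohort

### Generative model

Every voxel timecourse is

    baseline + noise_sd * white_noise
             + a(region, hemi, condition) * noise_sd * s_region(t)
             + slope * t + quadratic(t) + physiological sinusoids

where `s_region` is one band-limited (0.01–0.08 Hz) Gaussian latent
signal *shared by the left and right boxes of a region* — the simplest
mechanism that produces bilateral synchrony with tunable detection power.
The coupling amplitude table implements the longitudinal design: `a =
1.2` (in units of noise SD) everywhere preoperatively, `a = 0` in the
right SI and right Hp on days 1 and 3, and restoration at the
preoperative amplitude on day 9 (configurable; the restoration amplitude
is a separate knob because "almost normal" recovery is a matter of
degree).

Defaults and why:

* **Grid and timing** — 96x96 in-plane matrix, 20 slices, 120 volumes at
  TR 2 s after 5 dummy scans; voxel 0.52 x 0.52 x 1 mm (a 50 mm
  field of view). The acquisition arithmetic of the emulated design is
  internally inconsistent about total scan time; the generator follows
  `n_volumes * TR` and ignores the stray total-seconds figure.
* **Coupling amplitude 1.2x noise SD** — after smoothing and filtering
  this yields voxel-level correlations near 0.9 with the seed reference,
  comfortably above the 0.606 threshold, so baseline counts saturate the
  region masks; this matches the published tables, where day-9 fractions
  cluster at 0.93–1.00 and day-1/3 fractions at 0.01–0.02.
* **Baseline 1000, noise SD 10** — 1% noise, so percentage signal
  fluctuations are on the familiar +/-2% scale.
* **Drift** — each run draws a linear slope uniformly from +/-0.05 units
  per volume (removed exactly by detrending). The planted outlier rat
  additionally receives a centred quadratic baseline with end-of-run
  excursion 50 units (5 noise SDs) on all its runs — "large nonlinear
  baseline drift" that linear detrending cannot remove.
* **Physiological components** — respiration ~1 Hz and cardiac ~5 Hz
  exceed the 0.25 Hz Nyquist limit and alias into the sampled series. The
  defaults, 1.05 Hz (amplitude 3) and 5.1 Hz (amplitude 2), alias to
  0.05 Hz — *inside* the LFF band, deliberately, so the pipeline must
  tolerate it — and 0.1 Hz, which the 0.08 Hz filter removes. Each voxel
  receives an independent uniform phase (vascular transit varies
  spatially), so physiological power does not masquerade as long-range
  synchrony; with a globally coherent phase an aliased in-band component
  of this amplitude would contribute a spurious interhemispheric
  correlation of ~0.2, which is the kind of artifact the design should
  represent as noise, not as signal.

### The toy atlas

Regions are axis-aligned boxes mirrored exactly across the midline. The
two seed points are only ~0.6 mm apart, which forces a deliberate
geometry: the SI box extends *medially* from the voxel containing its
seed and the Hp box *laterally*, with y and z centred. The default extent
is 8x8x3 voxels — 8 is the largest in-plane extent for which the left SI
box stays clear of its own right-hemisphere mirror on the default grid
(a 10-wide box would cross the midline). `make_atlas()` validates
containment and pairwise disjointness and errors naming the offending
region.

Grid resolution interacts with this geometry: at half resolution
(48x48x10) the SI and Hp seed points fall into the *same* voxel and no
disjoint atlas exists — `make_atlas()` correctly refuses. The reduced
grid used for cohort-scale computations is therefore 64x64x14 (region
boxes 6x6x3), the 2/3-scale grid on which the seeds still separate. The
acceptance script and the cohort-level tests use this grid with the full
18-rat cohort; all statistics are normalized fractions, insensitive to
the absolute voxel count.

### Drift-outlier exclusion

The exclusion statistic fits `intercept + linear + quadratic` to the
brain-mean timecourse and measures the quadratic excursion
`|c2| * ((T-1)/2)^2` in units of the linearly-detrended global SD. Its
null distribution (measured on 500 outlier-free runs during design) has
mean ~0.22, SD ~0.18 and was never observed above 1; the planted outlier
scores ~3.3 almost deterministically, because for large drift the
quadratic dominates the denominator too, saturating the ratio near 3.3.
The default threshold is 2.0: more than five null SDs above the null
bulk, 36% below the planted score. (A threshold of 1.0 would produce on
the order of one false exclusion per ~1000 clean runs — measurably unsafe
for a zero-false-exclusion requirement.) A rat is excluded when any of
its runs exceeds the threshold.

### Voxel scaling and smoothing

Rodent data are conventionally analysed with header voxel sizes inflated
10x so human-calibrated tooling behaves sensibly; a "7.8 mm" kernel then
means 7.8 mm *in scaled units*, i.e. ~1.5 in-plane voxels (~0.8 true mm).
`smooth_run()` itself is agnostic (`voxel_scale = 1` applies true
millimetres); the pipeline default is `voxel_scale = 10`. This matters:
at true scale a 7.8 mm kernel (sigma ~6.4 voxels) would smear seed signal
across the midline and between adjacent SI and Hp boxes, destroying the
very contrast the analysis measures. The choice is recorded in run
metadata.

## Numerical choices

* **Ideal FFT filter, not Butterworth** — only a cutoff is specified; the
  ideal zero-phase filter makes the effective-df argument exact and the
  unit tests deterministic. On 4D runs the filter is applied as a
  projection onto the retained real Fourier basis, which is
  mathematically identical to the FFT route (verified to 1e-12 relative
  in the tests) and several times faster.
* **mm-to-voxel mapping** — affine inversion to a continuous index, then
  `floor(c + 0.5)`: each voxel owns the half-open mm interval centred on
  it. Deterministic, exact round trip on voxel centres.
* **Smoothing boundaries** — nearest-edge replication with a truncated
  (4 sigma), renormalized kernel: constants are preserved exactly and
  interior mass is conserved.
* **Degenerate inputs** — zero-variance voxels are undefined (`NA`),
  never 0; a seed whose reference cancels to zero variance raises a
  degenerate-seed error; group-map voxels with zero cross-rat variance
  are undefined unless the mean is also zero.
* **Detrend/low-pass ordering** — detrending precedes filtering (the
  order the original toolchain implies). The two operators commute only
  on series that are both trend-free and band-limited; on general input
  the difference is O(amplitude/n), which is why the order is fixed
  rather than treated as interchangeable.
* **Determinism** — every run's seed derives deterministically from the
  master seed and the (rat, session) index; whole-cohort generation and
  the full pipeline are pure functions of `(config, seed)`.

## What the generator does not emulate

No head motion, scanner spikes or ghosting, no slice-timing offsets, no
spatially structured physiological noise (beyond per-voxel phase), no
hemodynamic response function, no anatomical contrast, and no spatial
normalization — synthetic data are born aligned. Consequently, passing
tests demonstrate that the *statistical machinery* is calibrated and that
the pipeline recovers a known longitudinal coupling pattern under
realistic noise, drift and aliasing; they do not validate motion
correction or registration, which are out of scope, nor guarantee
performance on real scans whose artifact structure is richer.

## Problem sizes used by the tests

The test suite and acceptance script choose sizes that preserve the
statistics while keeping the arithmetic small: unit tests run on 32x32x8
or 24x24x6 grids (the smallest on which the atlas geometry is
well-posed), cohort-level checks on the 64x64x14 grid with the full
18-rat, four-session design, null calibration at 1e5 pairs for moderate
tails and 1e6 pairs for the 2.5e-5 mapping threshold, drift-exclusion
replication at 20 cohorts of 12 rats, and the behavioural power check at
100 replicates of 18 rats per condition.

## A worked example

```{r example}
library(lffconn)

cfg <- study_config(reduced = TRUE, rng_seed = 1)
ex <- run_experiment(cfg)
print(ex)

## Tables analogue: cohort means of normalized supra-threshold counts
subset(ex$summary, region == "SI_R")

## interhemispheric timecourses and spectra for the designated rat
str(ex$spectra$preop$SI, max.level = 1)

## behavioural arm
ex$ymaze$F; ex$ymaze$p; ex$ymaze$contrasts

write_report(ex, "lffconn-report")
```

## Known limitations

* The effective-df rule is an approximation whose exact counterpart (t
  with 37 df here) is known for the ideal filter; for other filter
  designs the rule would need re-calibration.
* The counting masks are the generator's own atlas boxes; on real data
  the analyst must supply masks, and counts depend on their extent.
* The Y-maze model is a truncated rounded normal — adequate for
  mean +/- SD emulation, not a cognitive model.
* Pairwise behavioural contrasts are unadjusted two-sample t tests; no
  multiplicity correction is applied anywhere, by design fidelity to the
  emulated analysis.
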