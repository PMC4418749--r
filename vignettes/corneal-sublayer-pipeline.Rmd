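---
title: "Corneal sublayer segmentation and repeatability statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corneal sublayer segmentation and repeatability statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cornoct)
```

## What the package models

`cornoct` re-implements, as a reusable and testable pipeline, the analysis
of central corneal sublayer thickness from ultra-high-resolution
anterior-segment OCT (UHR-OCT) B-scans, in the setting of thin-flap
refractive surgery (sub-Bowman's keratomileusis, SBK). A UHR-OCT B-scan of
the cornea shows a stack of specular interfaces along each axial scan
(A-scan): air–epithelium, epithelium–Bowman's layer, Bowman's
layer–stroma, the flap interface after surgery, and
endothelium–aqueous. The sublayer thicknesses of clinical interest are

* epithelium: air–epithelium to epithelium–Bowman's,
* Bowman's layer: epithelium–Bowman's to Bowman's–stroma,
* flap: air–epithelium to the flap interface (post-operative only),
* total cornea: air–epithelium to endothelium–aqueous.

OCT measures *optical path length*; geometric thickness is optical
distance divided by the corneal group index, fixed at 1.376 throughout.

Because no raw images from the underlying study are publicly deposited,
the package ships a first-class synthetic B-scan generator with exact
ground truth, and every downstream stage (segmentation, thickness
conversion, repeatability and longitudinal statistics) is validated
against that generator.

## Instrument geometry

The default `optical_geometry()` reproduces the study instrument: 1365
depth pixels over 2.01 mm and 2048 lateral pixels over 8.41 mm, i.e. an
axial pitch of 2010/1365 ≈ 1.4725 µm per pixel and a lateral pitch of
8410/2048 ≈ 4.106 µm per pixel, with a 3 µm axial point-spread FWHM in
tissue and group index 1.376.

A deliberate convention, applied consistently by generator and segmenter:
the depth axis stores optical path length, and all conversions to
geometric micrometres happen once, in `interfaces_to_thickness()`. Whether
the instrument's quoted 2.01 mm depth span is optical or geometric is not
decidable from the published description; since only interface
*differences* enter any statistic and both sides of the pipeline share the
convention, the choice is internally consistent and harmless.

Indices in this package are 1-based R conventions; interface depths are
sub-pixel row coordinates.

## The synthetic generator

`generate_bscan()` renders each interface as a ridge whose axial
cross-section is a Gaussian with the PSF's FWHM, following the anterior
curvature (default radius 7.8 mm, a typical human anterior cornea;
configurable) plus parallel offsets for the inner interfaces. A weak bulk
backscatter (4% of the brightest interface) fills the stroma. Optional
artifacts emulate what the real instrument produces:

* `"reflex"`: a saturated vertical band at the apex where the beam hits at
  normal incidence,
* `"hbands"`: horizontal artifact lines spanning the full width.

Speckle is modelled as multiplicative exponential noise on the noiseless
image plus a small additive Gaussian background — the standard
single-look speckle caricature, not a wave-optics simulation.
`noise_level` interpolates linearly between noiseless (0) and fully
developed speckle (1, the default). The study quotes no SNR figures, so
the default noise is calibrated only by the requirement that it be severe
enough to be visually realistic (per-pixel SNR of 1) while the published
3 µm axial resolution remains the relevant accuracy bound.

Two modelling notes:

* With the default 7.8 mm radius over the full 8.41 mm scan width the
  corneal periphery necessarily leaves the 2.01 mm raster, exactly as in
  the real images; the renderer clips it silently. A geometry error is
  raised only when interfaces inside the *central analysis span* (the
  exclusion window plus the two 0.5-mm flanking regions) would leave the
  raster, since that is what invalidates a measurement.
* Microdistortions — the fine wrinkling of Bowman's layer and the flap
  seen after flap repositioning — are modelled as an in-phase sinusoidal
  perturbation of the epithelium–Bowman's, Bowman's–stroma and flap
  boundaries (amplitude 0 disables). The generator can inject them; no
  counting statistic is implemented.

### Cohort simulation

`cohort_design()` / `generate_cohort()` simulate the longitudinal study
design: two groups (microkeratome "Moria", n = 20; femtosecond laser
"FEMTO", n = 21), five visits (`PRE`, `1D`, `1W`, `2W`, `1M`), two scan
repetitions per visit. `default_cohort_design()` is parameterised directly
from the published group summaries: per-visit means and cross-sectional
SDs, consecutive-visit change SDs, and week-1 test–retest difference SDs.
(One published cell, the FEMTO total-cornea SD at two weeks, prints as
237.4 µm amid neighbours near 37; it is treated as a typo for 37.4.)

Subject anatomy is drawn as positive building blocks — epithelium,
Bowman's layer, the stromal part of the flap, and the residual stroma —
so the ordering epithelium + Bowman's < flap < total holds by
construction. Component SDs come from the designed per-layer SDs by
variance subtraction (floored at 20% of the layer SD), which preserves
the designed marginal layer SDs while keeping subjects anatomically
coherent; intercepts are truncated at a 1 µm component floor, a
negligible tail (< 0.5%) of the normal model. Each visit adds a
within-subject fluctuation derived from the change SDs
(`Var(change) = 2·sd_visit² + pair_diff_sd²/2` for two-scan visit means),
and each scan adds independent repeatability noise with SD
`pair_diff_sd/√2`, so the difference of a visit's two scans has exactly
the designed pair SD. These defaults *are* the study conditions; they are
not tuned per analysis.

What the generator does not emulate: eye motion between A-scans, axial
bulk motion between repetitions beyond the thickness noise, pathology,
tear-film dynamics, peripheral limbal anatomy, and instrument roll-off.
Passing tests therefore demonstrate correctness of the algorithms under a
controlled, idealised image model — not clinical performance on real
scans.

## Segmentation

`segment_bscan()` follows the published processing order:

1. **Denoising** — separable uniform smoothing (3 px axial × 5 px
   lateral), symmetric and therefore location-preserving on ridge maxima.
2. **Horizontal artifact removal** — for each row, a robust baseline (the
   median over columns where that row lies in air above the detected
   anterior surface, or below the plausible posterior band) is
   subtracted. The estimate needs at least 50 qualifying columns,
   otherwise the row is left untouched; on a flat cornea the rows inside
   the corneal band therefore pass through unchanged, keeping the filter
   harmless on artifact-free images. Anterior detection runs twice: a
   first pass delimits the corneal band for the baseline, and a second
   pass on the cleaned raster provides the trace used for alignment —
   without the second pass, an artifact line in air can masquerade as the
   surface.
3. **Specular reflex exclusion** — the reflex is located as the column of
   maximal smoothed column energy, declared present when it exceeds 3×
   the median column energy, and the central 128 columns (0.5 mm) around
   it are excluded (left-biased by one column for the even window). When
   no reflex is present the window centres on the apex, the shallowest
   point of the anterior surface (ties, e.g. a flat phantom, resolve to
   the midmost column).
4. **Longitudinal profiles** — in each 0.5-mm flanking region the A-scans
   are aligned to the local anterior ridge by integer shifts and
   averaged. Integer (rather than interpolated) shifts add at most a
   uniform ±0.5 px jitter, broadening the averaged peak by ~5% while
   avoiding interpolation smoothing; speckle contrast falls by ~1/√122
   for the default region width.
5. **Ordered peak assignment** — local maxima of the averaged profile
   (lightly smoothed, 3 px) above a prominence floor are assigned in
   depth order: the strongest peak is the anterior surface; then
   epithelium–Bowman's within 35–75 µm of it; Bowman's–stroma within
   8–30 µm further; the flap within 70–140 µm of the surface (and at
   least 8 µm beyond Bowman's–stroma, since the two windows overlap);
   endothelium–aqueous within 350–700 µm of the surface. The anatomical
   windows resolve the ambiguity of a bare "k-th peak" rule under
   spurious peaks; their defaults bracket published anatomy (epithelium
   ≈ 50–52 µm, Bowman's ≈ 8–20 µm, SBK flaps ≈ 90–110 µm). Within a
   window the *shallowest* sufficiently prominent candidate wins —
   depth order is the primary rule; a relative prominence floor (30% of
   the strongest in-window candidate) rejects residual speckle bumps.
6. **Sub-pixel refinement** — a parabola through the peak and its two
   neighbours.
7. **Averaging** — the two flanking regions' interface sets are averaged
   into one central measurement per scan, matching the single central
   thickness reported per scan. Peak detection runs on the averaged
   profile (not per A-scan), which is the numerically stabler reading of
   the published description.

The prominence floor defaults to 3× a robust noise SD taken from the
profile tail beyond any plausible cornea; when the raster is too shallow
to have such a tail (reduced test geometries), a scale-free fallback,
`mad(diff(profile))/√2`, is used.

If peaks cannot be assigned, `detect_interfaces()` raises a classed
segmentation failure carrying `qc_flags` — the hook for the manual
fallback (`apply_manual_override()`), which replaces chosen interfaces
and marks their provenance `"manual"`. In cohort assembly, failed scans
are excluded and counted in the QC report; repeatability analysis then
drops the affected visit pair (both scans), since the statistics are
defined on complete pairs.

## Statistics

With `d_i` the paired difference of a subject's two measurements:

* **CoR** = 2·SD(d) (sample SD, n−1 denominator — the convention that
  round-trips the published table, e.g. SD 2.00 → CoR 4.00);
* **CoR%** = CoR / mean of all first and second measurements × 100;
* **95% LoA** = mean(d) ± 1.96·SD(d), the multiplier fixed at 1.96;
* **ICC** = two-way, absolute-agreement, single-measures ICC(A,1) from
  the two-way mean squares. The original analysis names no ICC variant;
  absolute agreement matches its stated purpose (difference variability
  against overall variability) and penalises systematic offsets between
  repetitions; a consistency variant is available. Published ICCs cannot
  be recomputed from printed summaries, so simulation-level recovery is
  what the tests assert.

Longitudinal analysis (`visit_changes()`): per consecutive-visit interval
the paired change mean ± SD; an omnibus one-way repeated-measures ANOVA
across visits (`aov` with a subject error stratum, no sphericity
correction by default — the original reports none); post hoc
consecutive-visit paired t-tests with Bonferroni correction over the
number of intervals. Between-group comparison
(`group_difference_ci()`): a pooled-variance Student t interval — the
variant that reproduces the published 1-day flap difference CI of
9.8 (4.8–14.8) µm from the group summaries — with Welch as an option.
`required_sample_size()` iterates achieved power under the noncentral t
distribution; the published minimum of 13 corresponds to the
one-sample/paired one-tailed configuration at d = 1.0, α = 0.05, power
0.95 (a two-sample two-tailed reading gives 27 per group), so the family
is an explicit argument rather than an assumption.

## Numerical choices and degenerate inputs

* Interface sets must be strictly increasing in depth; violations are
  validation errors, not silent reorderings.
* Parabolic refinement falls back to the integer peak at profile borders
  or non-concave vertices.
* Repeatability statistics require ≥ 2 pairs (≥ 3 subjects for ICC);
  zero total variance makes the ICC undefined (an error, not NaN).
* A two-visit cohort yields the single paired change with no omnibus
  ANOVA (reported as `NA`).
* Images narrower than the exclusion window plus both flanking regions
  (372 columns at native pitch) are rejected with a geometry error.

## Problem sizes used in validation

The packaged tests validate at sizes chosen to make Monte-Carlo
assertions sharp while remaining quick to run: noisy-image accuracy on 50
native-geometry B-scans (mean absolute thickness error ≤ 3 µm, the
instrument's axial resolution; observed ≈ 0.1 µm), sub-pixel oracle
equivalence on noiseless profiles (≤ 0.2 px), repeatability-statistic
recovery over 200 replicate cohorts at the published design SDs (within
3 Monte-Carlo SEs, with the c4 small-sample SD bias accounted for), and
post hoc type-I error under 150 null cohorts. Unit tests use a reduced
raster (700 × 512) with the native pixel pitches, so all physical-unit
logic is identical to the full geometry.

## Known limitations

* The generator's speckle is uncorrelated between pixels; real OCT
  speckle has a correlation length set by the PSF. Averaged-profile noise
  is therefore somewhat optimistic at fixed `noise_level`.
* Segmentation accuracy is reported against the generator's own image
  model; no claim is made about real UHR-OCT scans, microdistortion
  quantification, or peripheral pachymetry maps.
* The row-baseline artifact filter only attenuates artifact lines inside
  the corneal band where enough air-reference columns exist at that row.
* PNG output is 8-bit (the `png` writer's depth); TIFF (16-bit) is the
  primary image format.
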