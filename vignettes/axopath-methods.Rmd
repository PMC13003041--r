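---
title: "axopath: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{axopath: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axopath)
```

`axopath` quantifies nigrostriatal degeneration in AAV-A53T α-synuclein
mouse models: axonal swellings in immunostained z-stacks, regional
optical densitometry, stereology, glial area fractions, and the
composite Axonal Degeneration Index (ADI). This vignette explains the
procedures, their assumptions, the tunable parameters, and the design
decisions taken where the methodology left genuine choices open.

## The swelling-quantification macro

Axonal swellings are focal dilations of degenerating axons, visible as
compact dark blobs in brightfield immunostains (bright objects after
contrast inversion). `quantify_stack()` applies a fixed operator chain to
each calibrated z-stack:

1. `to_uint8()` — linear rescale of the stack range to 0–255, rounding
   half away from zero; a constant stack maps to 0.
2. `invert()` — `v → 255 − v`, so staining becomes bright signal.
3. `rolling_ball_background()` — slice-wise grayscale opening with a
   *ball-height* structuring element: the background is the surface
   traced by a ball of the given radius rolling under the intensity
   landscape. We implement the true ball-SE opening rather than the
   historical paraboloid approximation used by some software; the two
   differ only in the curvature profile of the removed background, and
   the opening form gives clean mathematical guarantees (anti-extensive,
   idempotent) that the test suite verifies against a brute-force
   erode-then-dilate oracle. Edges are handled by restricting the
   element to in-bounds offsets, which preserves anti-extensivity.
4. `subtract_constant()` — "pixel subtraction": removes residual diffuse
   staining (and faint fibre signal) that survives background
   subtraction. Default 50 of 255.
5. `median_filter()` — disc neighbourhood, default radius 1 pixel,
   reflective (half-sample symmetric) padding.
6. `enhance_contrast()` — linear stretch mapping the `s` and `1 − s`
   intensity quantiles to 0 and 255; default saturation `s = 0.0035`,
   the common auto-contrast convention. A degenerate quantile range
   leaves the image unchanged with a warning.
7. `moments_threshold()` — Tsai's moment-preserving threshold (the
   "Moments" method of common image software): the two representative
   levels and the background fraction `p0` that preserve the first three
   gray-level moments are computed in closed form, and the threshold is
   the smallest bin whose cumulative histogram fraction reaches `p0`.
   The threshold is invariant under uniform scaling of the histogram.
   Foreground is `value > threshold`.
8. `connected_components()` — 26-connected 3-D labelling (built on an
   adjacency graph; a depth-1 stack reduces to 8-connected 2-D), with
   per-particle voxel count, physical volume
   (`voxels × pixel_size² × z_step`) and maximum single-slice
   cross-sectional area.

A particle counts as a swelling only if its maximum single-slice
cross-section is **strictly** larger than `min_area = 0.53 µm²` and it
has **at least** `min_voxels = 5` voxels. The stated filters mix units —
an area in µm² and a count in voxels — and the only reading that uses
both is to apply the area test to the particle's largest cross-section
and the voxel test to the full 3-D component; that is the default. An
alternative reading, in which particles are 2-D objects of the
maximum-intensity projection, is available via
`swelling_params(projection = TRUE)` for comparison. The strictness
convention follows the wording: "larger than" is strict, "a minimum
of 5" is not.

The subtraction constant, median radius, contrast saturation, and the
macro's rolling-ball radius are not fixed by the published workflow
description; they are exposed in `swelling_params()` with the defaults
above, and the same settings are applied to every stack of a batch (the
per-stack threshold is recorded in each result). The threshold method is
stated explicitly only for the glial workflow; we default the swelling
macro to the same Moments method, selectable in the parameters.

Per-animal summaries (`summarize_animal()`) sum counts over stacks
(typically 12: six sections × two hemispheres) and take the median of
the pooled particle volumes; an even-sized volume set uses the mean of
the two central values, and an empty set flags the median as undefined
rather than inventing a value.

## Region-level quantification

`optical_density()` measures a region's mean staining intensity minus
that of an anatomical background region (corpus callosum or the basal
cerebral peduncle) on the same scanned section. Scanned DAB sections are
brightfield, so images are inverted first (configurable): more staining
then means larger OD. The value may be negative and is reported as such;
it is invariant to adding a constant to the whole image. Per-animal
values (`animal_region_od()`) are means over that animal's sections; the
section count is recorded. OD units are arbitrary scanner units — no
absolute calibration is attempted.

`positive_area_fraction()` runs the glial batch settings — rolling ball
radius 20 px, Gaussian blur σ = 2 px, automatic contrast, Moments
threshold — and reports the thresholded foreground fraction and absolute
positive area in mm². One degenerate case deserves mention: a uniformly
saturated image has, by construction of background subtraction, *no*
structure smaller than the ball, so the pipeline reports fraction 0, not
1 — area-fraction methods are meaningful only for structured images, and
the test suite therefore validates against images with programmed
sub-ball-size object coverage (recovered within ±0.02) and a
monotonicity property instead.

`optical_fractionator()` implements `N = ΣQ/(ssf · asf · hsf)` with
`asf = frame² / step²`. The phrase "separation between dissectors of
60 µm" is ambiguous between an inter-frame gap and a full grid step; we
read it as the gap (step = 50 + 60 = 110 µm), because a 60 µm step would
be smaller than the 50 µm frame. The alternative is available via
`stereology_params(separation_is_step = TRUE)`, which rejects steps
smaller than the frame. Dissector counting rules (inclusion/exclusion
lines) are applied upstream by the person counting; counts arrive here
as data. `cavalieri_density()` estimates the reference volume as
`Σ areas × thickness / ssf` and divides `N` by it.

## The Axonal Degeneration Index

TH optical density falls monotonically as fibres are lost, while
swelling counts follow an inverted-U (low before damage, peaking during
active degeneration, falling again once fibres fragment). A single
animal with few swellings may therefore be either early or end-stage;
TH separates those cases. `zscore_by_timepoint()` standardises both
measures within each time point using the sample SD, across A53T
animals only: empty-vector controls present no axonal swellings and are
not imaged, so they have no swelling data to standardise. (Whether to
include controls is in principle open; the A53T-only choice is the one
consistent with controls lacking swelling counts, and
`group_filter = NULL` selects the alternative.) Strata with fewer than
two animals or zero variance raise errors naming the variable and time
point.

`stage_classify()` applies the threshold rules (defaults in
`staging_rule()`):

* stage 1 (early): `th_z > 0.3` and `sw_z < −0.5`;
* stage 3 (advanced): `th_z < −0.3` and (`sw_z > 0.5` or `sw_z < −0.5`);
* stage 2 (intermediate): `−0.3 ≤ th_z ≤ 0.3`, any swelling.

The quoted inequalities are strict, and stage 2's interval is closed, so
the three rules do not tile the plane: combinations such as high TH with
unremarkable swelling, or low TH with moderate swelling, match no rule.
These fall back to stage 2 — intermediate is described as having
"variable swelling" and is the natural catch-all. The fallback score is
configurable and the number of fallback assignments is attached to the
result. Rules are evaluated in the order 1, 3, 2, fallback, which a grid
scan over `[−3, 3]²` at step 0.01 confirms is total and single-valued.
The per-animal ADI is the stage score; group summaries are arithmetic
means ± sample SD, and sex comparisons use the Mann-Whitney U test.

`reconstruct_stage_scores()` closes the loop on published summaries: for
a printed mean ± SD of `n ≤ 15` scores in {1,2,3} it enumerates all
multisets whose mean matches at the printed precision and ranks them by
SD distance, reporting ties explicitly. A noteworthy property of this
enumeration: for the 60-day groups (2.6 ± 0.6 and 1.6 ± 0.6, n = 5) the
nearest admissible vectors both have sample SD 0.548, not 0.6 — the
printed SDs are evidently rounded from a different convention or carry a
transcription quirk; the reconstruction keeps the nearest-SD vectors and
does not "correct" anything.

## Statistics

`mann_whitney()` reports `U = R_x − n_x(n_x+1)/2` from midranks, with a
two-sided p-value from the tie-corrected normal approximation with 0.5
continuity correction; for pooled samples of at most 12 without ties it
switches to exact enumeration. The computation delegates to
`stats::wilcox.test()` (which implements exactly these conventions) with
the U statistic recomputed independently from midranks as a consistency
guard; tests verify U against a brute-force pair-counting oracle and the
Monte-Carlo type-I error under the null. `shapiro_wilk()` wraps
`stats::shapiro.test()` (Royston's algorithm, valid for n between 3 and
50), with an explicit error for zero-variance samples.

`two_way_anova()` fits `response ~ group * sex` by least squares and
computes Type II sums of squares as nested-model RSS differences (each
term against the model containing the terms it is marginal to). This
route — rather than an off-the-shelf ANOVA table — is deliberate: it
remains well-defined for degenerate inputs (a constant response, or an
exactly additive response with zero residual) where standard
implementations refuse to divide by a zero residual; the SS are still
reported with the F left undefined. On non-degenerate unbalanced data
the results are verified in the test suite against `car::Anova(type = 2)`
to 1e−10, and on balanced data against the classical closed-form
decomposition. Type III via sum-to-zero contrasts is selectable; each
time point is analysed independently (no repeated-measures modelling —
animals are cross-sectional). Log transformation of the response is an
explicit flag, never automatic, and is recorded in the result notes.
`ancova()` adjusts a group effect for a covariate (body weight) the same
way. `power_sample_size()` implements the corrected normal
approximation `n = 2(z_{1−α/2} + z_{power})²/d² + z²_{1−α/2}/4`; at
d = 1.5, α = 0.05, power 0.8 this gives 7.94 ≈ 8 per group, alongside
the exact noncentral-t solution.

## Synthetic data: what it emulates and what it does not

`generate_image_stack()` emulates the acquisition geometry of the
swelling data: 0.1 µm/pixel (a 60× oil objective with a typical camera)
and a 1 µm z-step, at which the 0.53 µm² area filter equals 53 pixels.
Fibres are rendered as curvilinear random-walk tubes of ~1-pixel
calibre; swellings as anisotropic Gaussian blobs truncated at 2σ —
smoother and more realistic under thresholding than hard ellipsoids —
with the ground-truth volume defined analytically from the σ used
(`4/3·π·r_xy²·r_z` with radii the 2σ extents). Object stamps combine by
pointwise maximum, so overlaps do not add. Two object classes are
generated: "large" swellings (default lateral radius 0.8–1.1 µm) that
exceed both particle filters, and "small" decoys (0.2–0.3 µm) that fail
the area filter; the stored `passes_filter` flags can be recomputed from
geometry with `recompute_filter_flags()`.

Rendering defaults to *brightfield*: a bright background (level 230)
with a smooth linear illumination gradient from which objects absorb
intensity, which is what the inversion step of the macro expects. An
additive *fluorescence* mode is provided for tests and other workflows;
in that mode, with no noise and flat illumination, the stack maximum is
exactly `background_level + fibre_intensity`. Objects are placed by
rejection sampling with a minimum separation (default 2.5 µm) and a
boundary margin equal to the truncation extent; by default failed
placements are redrawn, or the generator can be configured to error.
The generator does not model a microscope PSF, depth attenuation,
chromatic effects or tissue autofluorescence — so detector performance
on these stacks bounds what clean, well-separated data allow and does
not certify performance on crowded or low-contrast real material.

`generate_cohort()` emulates the study design: sex × treatment (A53T vs
empty vector) × time points (60, 120 days), five animals per cell. TH OD
is normal around a sex- and time-dependent mean (baseline 100 arbitrary
units, SD 5; male declines 30 then 45 units, female 10 then 40 — males
degenerate earlier, the sexes converge later). Swelling counts are
negative-binomial (the published account states no count distribution;
negative-binomial mean/dispersion is our choice for overdispersed
biological counts, dispersion 10) around a sex-specific inverted-U
profile `peak · exp(−((t − peak_t)/width)²)` with the male peak at 60
days, female at 120, peak mean 150 and width 60 days. Empty-vector
animals have structurally zero swelling counts and baseline TH. Body
weights are sex-specific normals (23 ± 1 g male, 19 ± 1.5 g female).
With these defaults, the mean male ADI exceeds the female at day 60 in
far more than 80% of simulation seeds and the sex gap shrinks by day
120 in the large majority — the qualitative pattern the index was built
to expose.

## Numerical conventions and degenerate inputs

* Rounding of intensities is always half-away-from-zero.
* Rolling-ball backgrounds are rounded to integers; the invariants
  `corrected ≥ 0`, `background ≤ original`, and
  `corrected + background ≥ original − 1` (one unit of rounding slack)
  hold everywhere, and re-opening a background reproduces it within one
  unit.
* Reflective padding is half-sample symmetric and tiles for kernels
  wider than the image (so very large blur sigmas approach the image
  mean).
* `moments_threshold()` resolves the p-tile lookup to the smallest bin
  whose cumulative fraction reaches `p0` (with a 1e−12 guard against
  floating-point shortfall); a single-populated-bin histogram returns
  that bin.
* Mann-Whitney exact enumeration is used only for small untied pooled
  samples; otherwise the tie-corrected continuity-corrected
  approximation.
* Medians of even-sized sets are means of the central pair; undefined
  medians (no particles) are flagged, not imputed.
* All randomness flows through explicit integer seeds in the simulation
  configs; generators restore the caller's RNG state, and fixed seeds
  give bit-identical outputs.

## Problem sizes used in the test suite

The suite validates the detector on 96 × 96 × 10 and 72 × 72 × 8 voxel
stacks (12 + 5 and 8 + 4 planted objects) over 20 seeds with noise SD up
to 4, achieving recall and precision of 1.0 against ground truth;
oracle comparisons use 32 × 32 slices for morphology, 16³ stacks for
connected components, and 500 sampling draws for fractionator
unbiasedness; cohort-level properties use 200 simulation seeds and 5 000
Monte-Carlo replicates for the Mann-Whitney type-I error. These sizes
were chosen so the full suite exercises every oracle at meaningful scale
while remaining comfortably runnable on a laptop.

## Known limitations

* The swelling macro is faithful to a batch-processing description that
  leaves four enhancement constants unstated; different choices shift
  absolute counts (the per-time-point z-scoring of the ADI absorbs
  monotone shifts, which is part of why the index is robust).
* No atlas registration or automatic ROI placement: ROIs are inputs.
* No cell detection for stereology: dissector counts are inputs.
* The 2-D projection mode is provided for comparison but the 3-D
  component reading is canonical here.
* Behavioural endpoints (open field, beam walking) are outside the
  scope of this package; cohort tables may carry them as extra columns
  for the statistics module, but nothing image-based is computed for
  them.
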