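---
title: "Methods: quantifying microtissue contractility on cantilever post arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying microtissue contractility on cantilever post arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement

A contractile microtissue is cast between two flexible elastomer posts
hanging into a well. As the tissue compacts and contracts it pulls the post
tips together, so the inter-post spacing is a force sensor read out by
brightfield imaging. `micropost` quantifies this readout end to end:

* **Tip distance.** The unseeded spacing `D0` is measured once at day 0; the
  spacing `Dt` is measured at readout. Both are the *minimum edge-to-edge*
  Euclidean distance between the two segmented post-cap masks
  (`tip_distance()`), computed with an exact Euclidean distance transform of
  one component sampled on the other. This equals the exhaustive pixel-pair
  minimum (the test suite checks exact agreement on random masks) while
  running in linear time.
* **Contraction.** `contraction_percent()` reports
  `100 * (D0 - Dt) / D0`, the deflection as a percentage of the original
  spacing. The same formula applied to a pre/post-stimulus pair gives the
  acute agonist response (`acute_response()`).
* **Force.** Deflections convert to force through a cantilever spring
  constant `k` (uN/um). Both posts are assumed to deflect symmetrically, so
  the per-post deflection is half the change in spacing and
  `force = k * (D0 - Dt) / 2` (`deflection_to_force()`, default
  `k = 0.109` uN/um, the device calibration; the `share` argument covers
  asymmetric devices). Negative deflections (relaxation past baseline) clamp
  to zero force and are flagged rather than reported as negative tension.
* **Tissue area.** Pixel count of the tissue mask from the F-actin channel,
  converted to mm^2 through the (binned) pixel size (`tissue_area()`).
* **Viability.** Mean in-tissue TMRM intensity rescaled linearly between a
  staurosporine-killed dead reference and a live reference, clipped to
  [0, 1]; scores below 0.2 are called dead (`viability_score()`).

## Image conditioning

Wells are acquired as overlapping fields of view with a small z-stack per
field. The conditioning chain (`preprocess_well()`) is: per-field flat-field
correction, stitching, maximum-intensity projection, optional mean binning —
in that order, so each field is corrected with its own shading estimate
before mosaicking.

**Flat-field correction** (`correct_shading()`) is retrospective and
single-image. The default estimator fits a quadratic polynomial surface with
one robust reweighting pass that discards pixels far from the first fit, so
dark caps and bright tissue do not drag the surface; this is exact for the
parabolic vignetting typical of microscope optics and unbiased at image
borders. Heavy Gaussian smoothing (`sigma = min(dim)/8`, normalised
convolution) is available as `method = "gaussian"` for smooth non-polynomial
fields; it carries a small boundary bias, which is why it is not the
default. The estimated gain is normalised to mean 1, preserving the global
intensity scale. A constant image returns an identity model with a warning
instead of failing.

**Stitching** (`stitch_fields()`) places tiles at nominal offsets
(`step = tile - round(overlap * tile)`) and refines each offset by
exhaustive integer-shift cross-correlation (default +/-5 px) against the
already-placed neighbours. A refined shift is accepted only when its
correlation beats the nominal placement by a clear margin (0.05): content
that is uniform along one axis — a tissue band crossing a seam — correlates
equally well at many shifts along that axis, and without the margin rule the
argmax wanders (we measured ~8% tissue-area inflation from exactly this
failure mode before adopting the rule). Sub-pixel registration is
deliberately out of scope: the features being measured are tens of pixels
wide. Overlaps are blended with a separable linear feather.

**Binning** (`bin_image()`) is mean pooling, not summation, so intensity
thresholds transfer between binned and unbinned paths and the global mean is
conserved exactly. Trailing rows/columns that do not fill a block are
cropped, deterministically. The full-scale mosaic is 2160 x 2160 px and the
tissue-area path runs on the 4 x 4-binned 540 x 540 image.

## Segmentation

The segmentation contract is backend-agnostic: anything producing per-pixel
probabilities over {background, post, tissue} can drive the downstream
rules. The canonical desk-scale backend (`train_pixel_classifier()`) is a
random forest over a multiscale feature bank (Gaussian, gradient magnitude,
Laplacian-of-Gaussian, difference-of-Gaussians at sigma 1-4 px plus raw
intensity), trained on labelled pixels sampled class-balanced from ground
truth masks and fixed by a seed end to end. A deep encoder-decoder can fill
the same slot; its published training configuration is recorded in
`unet_backend_defaults()` but no GPU training happens here. A
classifier-free threshold baseline (`clf = NULL`) exists for clean images
and for cross-backend agreement tests.

Rule-based QC then enforces the geometry instead of trusting the classifier:

* `segment_posts()` fills holes, drops components outside
  `[0.25, 4] x` the expected cap area (tolerating defocus growth without
  admitting tissue fragments), keeps the two largest survivors, and flags
  `no_posts`, `wrong_count`, `undersized`, `oversized`. Exact area ties
  beyond two candidates break toward the horizontal midline, where the posts
  sit by construction.
* `segment_tissue()` keeps the largest tissue component and flags
  `tissue_absent` and `tissue_touches_border` (the detachment signature).

Failures always surface as QC flags; no well is silently dropped.

## The synthetic-data generator

Every stage above is validated against `generate_scene()`, which renders a
well with *known* truth: two dark elliptical caps (radius 200 um) on a
bright background separated by a configurable edge-to-edge tip distance
(default 1800 um), an optional tissue band with a quadratic waist profile
bridging the caps, per-field quadratic vignetting (multiplicative, amplitude
0.15), additive Gaussian noise (sd 0.01 on a 0-1 intensity scale), a 2 x 2
field grid of 1137 px tiles at 10% overlap (a 2160 x 2160 stitched mosaic at
1.35 um/px), 3 z-planes with out-of-focus planes uniformly dimmed, and
F-actin / TMRM channels encoding tissue extent and viability. The requested
tip distance is snapped to a whole pixel and the recorded truth is the
snapped value, so the ground-truth masks measure *exactly* their recorded
distance. The tissue band's analytic area (from the waist profile) agrees
with the rasterised mask within 2%.

Tests and the analysis scripts run a desk-scale variant (288 px tiles,
5.4 um/px — the same physical geometry at 4x coarser sampling) so the whole
suite finishes in minutes; the full-scale default is exercised where only
size matters (binning, mosaic geometry).

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: cell-scale texture, defocus blur and other PSF
effects, post shadows and meniscus artifacts, autofluorescence, debris, or
non-polynomial shading. On real images the classifier needs real labelled
pixels, and recovery will not be near-exact as it is here; the synthetic
scenes establish correctness of the machinery, not field performance.

`simulate_screen()` extends the generator to plates: each well draws its
true contraction from its condition's `(mean, sd)` effect model, damaged and
dead wells are flagged in truth, and rendered mode back-computes each well's
tip distance from its sampled contraction. Identical seeds give
bit-identical images and tables.

## Screening analytics

`aggregate_and_exclude()` removes damaged/detached wells (QC flags) and dead
wells (viability), averages technical replicates into biological values, and
summarises conditions by the median over biological replicates. Fully
excluded conditions are reported, never dropped. `call_hits()` then applies
the robust rule: a condition is a hit iff its summary contraction falls
*strictly* below `control_median - k * MAD`, with `k = 3` and the MAD the
**raw** median absolute deviation of the control values — no 1.4826
normal-consistency factor, since the summary statistic reported alongside it
is `median +/- MAD`. The rule is one-sided: the screen looks for suppressed
hypercontractility.

The canonical simulated screen (`kinase_screen_design()`) fills a 96-well
plate with an 18-well treated-control group (each well its own biological
value, since the MAD is computed over control wells) and 13 compounds at 6
wells each — two biological replicates, each the mean of three technical
wells, the minimum replication used in practice. Replication is what makes
the 3 x MAD rule specific: the threshold margin is about 2 control-SDs, so a
*single-well* condition at the control mean breaches it with >= 2%
probability no matter the noise level, and a plate of ~70 single-well
conditions would average several false positives. With condition summaries
averaging 6 wells the per-condition false-positive rate drops below 0.2%,
and the simulated screen recovers all injected actives with no false
positives in >= 95 of 100 seeds (measured 96-100% across independent seed
blocks), while the null-screen hit rate stays near 1%.

`filter_deg_table()` implements the companion expression filter: retain
genes with `p < 0.05` and `|log2 FC| > log2(1.5)` (= 0.585 at 3 decimals),
both inequalities strict so boundary rows are handled reproducibly;
malformed rows are rejected per row and counted.

## Mechanics

`beam_spring_constant()` treats a post as an end-loaded Euler-Bernoulli
cantilever: `k = 3 E I / L^3` with `I = w t^3 / 12` (rectangular) or
`pi r^4 / 4` (circular). A spring constant in N/m is numerically identical
in uN/um, so no unit conversion is applied; the worked 1 x 1 x 10 mm beam at
E = 1.33 MPa gives k = 0.3325 in either unit. `tip_deflection()` is the
exact inverse. Poisson's ratio (0.499 for the near-incompressible device
elastomer) and density ride along on `beam_spec()` for fidelity to the full
material model but do not enter the statics; large-deflection and
shear-corrected (Timoshenko) theory are out of scope, consistent with the
device's observed linear, symmetric deflections. The published device
calibration k = 0.109 uN/um is used as a configuration constant for force
conversion — post geometry is not part of this package's inputs, so the
closed form is not asked to reproduce it.

`analyze_tensile_curve()` reports Young's modulus as the least-squares slope
of stress on strain over the small-strain linear region (default
`strain <= 0.1`, the standard modulus convention for elastomers that
stiffen beyond) and the ultimate tensile strain at failure. When no failure
index is supplied, a tear is the first > 20% drop from the running stress
maximum *after* the sample is meaningfully loaded (running maximum above a
quarter of the curve's peak) — the guard keeps noise around zero stress at
the start of the ramp from reading as a tear.

## Numerical conventions

* Pixel coordinates are 0-based row-major in all reported witness
  coordinates; distances are between pixel centres. Ties in the minimum
  distance do not affect the scalar; the reported witness pair is the
  lexicographically smallest for reproducible overlays.
* Cap rasterisation keeps the boundary pixel placed exactly at one radius
  inside the cap (a 1e-6 px^2 tolerance absorbs floating-point rounding), so
  mask distances hit the snapped truth exactly.
* The tissue band rasterises a column of half-width `h` as ~`2h` pixels
  (area-consistent), which is what keeps the analytic-vs-mask area gap
  within 2%.
* All stochastic steps (scene noise, pixel sampling, forest growth, screen
  effects) flow from explicit integer seeds; RNG state is saved and restored
  around every seeded operation, and forests run single-threaded so
  predictions are bit-reproducible.
* Strict inequalities everywhere a threshold is applied (hit calling, DEG
  filter, dead-well cutoff).

## Known limitations

Single-image flat-field estimation cannot separate a gain field that mimics
real image structure; the multi-image low-rank approach used by dedicated
shading tools is out of scope, as are subpixel registration,
lens-distortion correction, 3D (z-resolved) distances, traction maps and
time-resolved force traces. Group inference on measured plates (ANOVA and
post-hoc comparisons) is left to standard statistical software; this package
stops at the robust hit list and the per-well measurement table.
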