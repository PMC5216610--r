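---
title: "Digital radiogrammetry of metacarpal cortical bone: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital radiogrammetry of metacarpal cortical bone: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dxr)
```

## The measurement problem

Radiogrammetry infers cortical bone mass from plain radiographs of the
hand by measuring, at the metacarpal shafts, the outer bone width $W$ and
the cortical thickness $T$ (one cortex; the combined cortical thickness is
$2T$). From these, a family of cortical indices is formed:

* the classical **metacarpal index** $\mathrm{MCI} = 2T/W$, dimensionless
  and therefore invariant to radiographic magnification;
* the **cortical area** $A = \pi T W (1 - T/W)$, which is exactly the area
  of an annulus with outer diameter $W$ and inner diameter $W - 2T$;
* the area-based index $\mathrm{MCI} = A/W^2 = \pi (T/W)(1 - T/W)$,
  also dimensionless, maximal at $\pi/4$ when the medullary cavity
  vanishes;
* the **bone health index** $\mathrm{BHI} = A / (W^{1.333} L^{0.333})$,
  which adjusts for patient size through the bone width *and* length $L$
  and is therefore *not* magnification invariant: uniform scaling of all
  lengths by $f$ multiplies it by $f^{2-1.666} = f^{0.334}$.

Periarticular cortical thinning is an early radiographic sign of
rheumatoid arthritis, so these indices are used as surrogate markers of
disease severity, conventionally summarised by the modified Larsen score
(32 joints, ordinal grades 0–5, patient summary = sum of points divided by
the number of evaluated joints).

Two ROI placement rules are implemented:

* **proportional** (`place_roi_bx()`): the region of interest is centred
  at 44% of the bone length from the proximal end and spans 25% of the
  length, i.e. the axial interval $[0.315, 0.565]$. Because it scales with
  the bone, it tolerates unknown magnification and caput erosions.
* **narrowest point** (`place_roi_xp()`): the ROI is centred where the
  measured width profile of the shaft (searched over axial fractions
  0.2–0.8) is minimal, with a fixed length of 30% of the bone length.

Because a narrowest-point ROI is on average longer and differently placed,
the thickness-ratio index measured by the proportional rule runs slightly
high against it; `mci_naive_adjusted()` divides by the empirical constant
1.084 to align the scales. The constant is data-derived and exposed as a
configurable divisor.

## The phantom: a projection model with exact ground truth

Clinical radiographs and the appearance-model landmarking used on them are
out of scope here; instead every pipeline stage is validated against
synthetic phantoms whose geometry is known exactly. A phantom metacarpal
is a tube of length $L$ whose outer radius $R(u)$ varies along the axial
fraction $u$ (a quadratic waist, narrowest mid-shaft by default) with a
cortical shell of thickness $T(u)$. Under a mono-energetic parallel
projection, a ray at transverse offset $x$ crosses cortical bone over

$$ p(x) = 2\sqrt{R^2 - x^2} - 2\sqrt{r^2 - x^2}\,[|x| < r], \qquad r = R - T, $$

and the rendered pixel is `background + p + N(0, noise_sd)` with the
attenuation gain fixed at 1 intensity unit per mm (only relative gradients
and opacities matter to the edge criteria). Three consequences make the
phantom a sharp oracle:

* the projected opacity is maximal exactly at $|x| = r$, so the "inner
  border at maximum radio-opacity" criterion is exact by construction;
* the total projected mass $\int p\,dx$ equals the annulus area
  $\pi T (W - T)$, tying the rendering to the cortical-area formula;
* bone ends are rounded by an elliptical cap over the outer 5% of the
  length, so the projected opacity falls to zero with infinite slope
  exactly at the anatomical end points — bone length is recoverable from
  the image rather than an artefact of thresholding.

Erosive defects (`apply_erosion()`) thin the cortical profile near one
end, over at most 20% of the length, leaving the proportional ROI interval
untouched — encoding the anatomical premise that caput erosions spare the
shaft.

What the phantom does **not** emulate: scatter, beam hardening, focal-spot
blur, soft-tissue anatomy, trabecular texture, carpal overlap, film grain.
Passing the recovery tests therefore demonstrates correctness of the
measurement chain under the projection model, not clinical performance on
real radiographs.

```{r}
spec <- phantom_bone_spec(60, 4.5, 4.0, 1.8, proximal_origin_mm = c(10, 6))
img <- render_phantom(spec, pixel_spacing_mm = 0.0846)
img
```

The default pixel spacing, 0.0846 mm, corresponds to the 300 dpi film
digitisation conventional for this measurement.

## Contour detection and bone length

Phantoms are high-contrast, so contours are found as closed iso-intensity
curves (`grDevices::contourLines`, which is already sub-pixel) at a level
placed **15% of the dynamic range above the background** (median of the
image border). A variance-based (Otsu) threshold was considered and
rejected: the projection profile has gradual square-root edges and a
medullary dip, and on rendered phantoms the Otsu level lands high enough
to split the two cortical strips of a thin-cortex bone into separate
components and to truncate the rounded ends by a couple of millimetres. A
low fixed-fraction level hugs the outline; it must only clear the noise
floor, which at the supported noise levels (≤ 2% of the cortical signal)
it does by a wide margin. Iso-contours nested inside another contour are
holes (a deep erosion can locally push the medullary stripe below the
level) and are discarded by an even-odd point-in-polygon test.

End points are refined in two iterations: project the boundary on its
principal axis for initial extremes, then localise each end along the
axis as the sub-pixel crossing of a noise-adaptive level just above
background (the capped tube's axial opacity rises with infinite slope at
the true end, so the crossing bias shrinks with the level). The boundary
is then resampled to the conventional 32 marks: each of the two arcs
between the end points is resampled at equal arc length (17 points
including the shared ends), so both anatomical end points are marks and
the bone length is exactly the distance between marks 1 (distal) and 17
(proximal). On noise-free phantoms the recovered length is within about
half a pixel of truth, comfortably inside the 1.5-pixel test bound.

## Border localisation on a scanline

Scanlines are sampled strictly perpendicular to the detected axis, one
per pixel row of the ROI, by bilinear interpolation. Each profile is
measured by the field's edge criteria: outer cortical border at the
maximum intensity gradient (rising on the left flank, falling on the
right; ties broken toward the outermost location), inner border at the
maximum radio-opacity of the cortex.

Sub-pixel refinement needs care because the projection profile is
*singular*, not smooth, at all four borders; a parabolic fit to the
discrete gradient (the textbook estimator) lands systematically about one
pixel inside the edge there, which is material at the precision the
recovery tests demand. The package therefore uses the projection geometry
itself:

* **outer borders** — near a projected circular edge,
  $1/\mathrm{gradient}^2$ is locally linear in position with root exactly
  at the border; the root of a line fitted on the singular flank (three
  samples) is the refined border. Residual bias is a few hundredths of a
  pixel.
* **inner borders** — around the opacity maximum, a one-parameter least
  squares fit of the annulus projection model (medullary radius $r$, with
  centre, outer radius and background anchored by the outer borders)
  via `stats::optimize`.
* parabolic interpolation remains the coarse locator and the fallback
  whenever a model fit degenerates (wrong-signed slope, root far from the
  coarse location, short window).

Two further numerical choices matter. First, each scanline's sample grid
is offset by a deterministic golden-ratio sub-pixel dither: a bone aligned
with the pixel grid would otherwise sample every scanline at the same
sub-pixel phase, and the phase-dependent part of the localisation error
would never average out across the ROI. Second, per-ROI aggregation uses
a central-80% trimmed mean over the valid profiles, guarding isolated
noise spikes; the ROI-level contract ("average T and W over the region")
is otherwise unchanged. The narrowest-point search deliberately does *not*
dither (it only needs the minimum's location) and refines it with a
quadratic fit of the width profile over the whole search interval, which
averages out the per-scanline discretisation wiggle; a profile flat to
within a quarter pixel has no defined narrowest point and tie-breaks to
the smallest axial fraction with a warning.

Degenerate inputs are classified rather than mis-measured: flat profiles
and monotone ramps raise a no-bone condition; a single central opacity
peak (no medulla left) marks the profile invalid with reason "cortices
merged"; border-ordering violations and thicknesses outside $(0, W/2)$
invalidate the profile. A ROI with fewer than 10 valid profiles errors.

Measured accuracy under these choices (asserted by the test suite): on 20
random noise-free phantoms, $T$, $W$, $L$ are each recovered within 2%
(typically well under 1%); at 2% image noise, within 5%; the
thickness-ratio index drifts by well under 1% between pixel spacings a
factor 1.25 apart; caput erosions of 80% depth move the proportional-ROI
index by under 0.5%.

## Self-validation

The measurement system this mirrors validates or rejects its own analysis
automatically, with an in-between "questionable" band referred to a
clinician — but publishes no criteria. The check set here is therefore
the package's own design, the largest gap filled by this artifact, and
every threshold is exposed in `validation_config()`:

* hard anatomical bounds (failure ⇒ **reject**): mean width in 4–15 mm,
  $T < W/2$, length in 40–90 mm (adult metacarpal ranges);
* soft quality bounds: coefficient of variation of $W$ across profiles
  ≤ 0.08, valid-profile fraction ≥ 0.8, contour fit residual ≤ 0.5 mm.

**Accept** requires every soft check to clear its threshold by at least
10% of the allowed interval's width; anything between accept and reject is
**questionable**. The margin rule is what creates the referral band: a
result just inside a quality bound is flagged for review rather than
silently accepted. Increasing image noise can only degrade the status —
a property the test suite checks across a noise sweep.

## The synthetic clinical study

`simulate_cohort()` generates the study population: per-patient severity
from a normal distribution with mean 2.6 and SD 1.3 (truncated to 0–5,
matching the severity profile of an established RA cohort), ordinal joint
scores scattered around it, an erosive-disease indicator whose probability
rises with severity (joint scores are constructed consistently, since
"any joint at grade ≥ 2" defines erosive disease), and cortical thickness
declining linearly with the damage score
($T = 2.25\,\mathrm{mm} - 0.15\,\mathrm{mm}\times\bar{S}$, scatter
0.08 mm) while width and length vary independently. Erosive patients
carry a distal caput defect in their ground truth. These couplings are
the generator's defaults and define the study conditions; they were
chosen once, from the cohort descriptives and from typical adult
metacarpal morphometry, not tuned to any downstream result.

`demo_study()` renders each patient's three-bone radiograph, runs both
ROI modes, and computes the study statistics: correlation of each index
with the mean damage score, bootstrap comparison of the two methods'
correlations, between-method agreement (SD of paired differences as a
percent of the mean), and the erosion contrasts. With 49 patients the
study takes on the order of a minute; the size is the cohort size the
statistics were designed around, and `n` is a parameter.

## Bootstrap comparison of dependent correlations

Two indices measured on the same patients are compared against a common
covariate by resampling patients (rows) with replacement, preserving the
pairing — the standard resampling scheme for dependent correlations. Per
replicate $d^* = r(x^*, y_A^*) - r(x^*, y_B^*)$; the two-sided p-value is
the percentile-interval inversion $2\min(\Pr(d^* \le 0), \Pr(d^* \ge 0))$,
and the reported *critical difference* is the half-width of the central
95% interval of $d^*$: an observed difference exceeding it in magnitude
corresponds (up to the asymmetry of the bootstrap distribution) to a 95%
percentile interval excluding zero. BCa corrections are deliberately not
used — the method mirrors basic resampling. Degenerate replicates
(zero-variance resamples) are redrawn, with a bounded retry count.
Calibration is checked by Monte-Carlo: under a constructed null (two
indices equally correlated with the covariate, $n = 49$, 2000 replicates,
500 trials) the empirical type-I error at $\alpha = 0.05$ must fall in
(0.03, 0.07) and the p-value distribution must be consistent with
uniformity (Kolmogorov–Smirnov at $\alpha = 0.01$; p-values are discrete
at 1/reps, so the KS check is conservative).

## File formats and reproducibility

Images travel with a JSON sidecar carrying the pixel spacing (the
measurement is meaningless uncalibrated: sidecar takes precedence over a
`spacing_mm` argument, and with neither, loading fails), the seed, the
intensity scaling, and the ground truth. 32-bit float TIFF round-trips
intensities to float precision; PNG output is 8-bit and intended for
viewing. All randomness flows through a single seeded Mersenne–Twister
stream per operation; rendering, the cohort, the study and the bootstrap
are bit-reproducible given their seeds, and package calls never disturb
the caller's RNG state.

## Known limitations

* The contour finder assumes high-contrast, non-overlapping bones; it is
  a phantom-grade stand-in for appearance-model landmarking and will not
  survive soft-tissue backgrounds, carpal overlap, or flexed hands.
* The inner-border refinement assumes the annulus projection locally; on
  real bone (elliptical cross-sections, trabecular signal) it degrades to
  the parabolic fallback.
* BHI's printed exponents 1.333/0.333 are used literally; exact thirds
  are available behind a flag and differ in the fourth significant
  figure.
* The validation thresholds are design choices, not estimates of any
  published system's behaviour.
* The adjustment divisor 1.084 is an empirical constant from the
  literature, not re-derived here; with phantom data both ROI rules see
  nearly identical geometry, so the adjusted index runs systematically
  low against the narrowest-point index on phantoms.
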