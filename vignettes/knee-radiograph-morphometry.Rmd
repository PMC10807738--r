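---
title: "Measuring knee osteoarthritis morphometry from landmarked radiographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring knee osteoarthritis morphometry from landmarked radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneemorph)
```

## The measurement problem

Radiographic follow-up of knee osteoarthritis rests on a handful of
quantitative parameters: the joint space width (JSW, a surrogate for
cartilage thickness), its minimum, the joint line convergence angle (JLCA,
a malalignment marker), the heights of the tibial intercondylar eminences,
and the subchondral bone density just beneath the joint surfaces. Manual
measurement of these quantities is slow and reader-dependent; `kneemorph`
computes all of them automatically from a posteroanterior knee radiograph
plus a 99-point bone-contour annotation produced by a statistical
shape-model tool. The package consumes that tool's plain-text point-list
output; it performs no landmark detection of its own.

Because the pipeline is fully deterministic — no RNG is consulted anywhere
between input and report — running it twice on the same inputs yields
bit-identical reports. That determinism is itself a headline property of
this class of measurement engines, and the test suite and
`scripts/acceptance.R` verify it directly.

## The measurement framework

All geometry happens in the image frame (x right, y down, 0-based pixel
centers) after canonicalization: left knees are mirrored about the vertical
midline so the lateral compartment always lies on the +x side. Four
supporting (tangent) lines are placed against named landmark regions:

* **L1** against the lateral tibial/femoral shaft contours (points 24–32,
  74–80, 90–98) from the lateral side;
* **L4** against the medial contours (2–7, 58–64) from the medial side;
* **L2**, the femoral joint line, against the condyle points (63–68,
  70–75) from the distal side;
* **L3**, the tibial joint line, against the anterior plateau points
  (9–13 and 20–25, with a 20–26 variant selectable) from the proximal side.

A supporting line is computed as the convex-hull edge whose outward normal
best aligns with the requested contact direction, with deterministic
tie-breaks (more touching points, then lowest touching index), so reruns
are bit-identical even on symmetric inputs. Corners `A = L3∩L1`,
`B = L3∩L4`, `C = L2∩L1`, `D = L2∩L4` define the scale lengths `AB` and
`CD`. Each compartment's measurement band runs from an outer perpendicular
at `2/15` of the scale length inward from the corner to an inner
perpendicular a further `3/20` inward. Tibial stations live on L3 and
femoral stations on L2 as separate arc-length coordinates: the two joint
lines are generally not parallel — that angle *is* the JLCA — so projecting
one band onto the other's axis would distort it.

The corner labelling (A lateral tibial, B medial tibial, C lateral femoral,
D medial femoral) is a package convention recorded in the framework object;
every fraction is symmetric in the corners, so the choice affects only
labels, never values.

## Joint space width

Thirty intra-articular circles are inscribed between the joint boundaries
— the condyle polyline above, the anterior plateau polyline below, clipped
to the compartment band (with linear extension of terminal segments, and a
quality flag, when the band outruns the annotated span). The paper-level
definition fixes the total of 30 but not their placement; `kneemorph`
places 15 per compartment at the midpoints of a uniform subdivision of the
band (`station_i = outer + (i + 0.5)/15 × bandwidth`), which is the only
symmetric reading and keeps circles off the band edges where clipping
artifacts live. The count per compartment is configurable.

Each circle's center is constrained to the perpendicular of L3 at its
station, so the diameter is a *local* width at a defined position rather
than a free-floating maximal inscribed circle. The radius of a candidate
center is its exact point-to-segment distance to the nearer polyline (no
sampling); the center position is optimized by a 33-point coarse scan
followed by golden-section search to well below 1e-4 px. When the
boundaries cross at a station the circle is reported with radius zero and
a crossing flag — never negative. Mean medial/lateral JSW are arithmetic
means of the 15 diameters times the pixel spacing; minimal JSW is the
global minimum of all 30.

## Subchondral bone intensity

Each radiograph carries an aluminum step wedge of known step thicknesses.
Within a user-supplied ROI the mean grey profile across the stripe
direction is clustered by 1D k-means (k = step count, evenly spaced
deterministic initial centers); the contiguous bands are eroded by a
sampling margin (default 2 px) and their mean greys become calibration
knots mapping grey → mm of aluminum equivalence (mmAl) by piecewise-linear
interpolation, clamped and flagged outside the knot range. Step thickness
is assumed to ascend along the profile axis in the canonical frame; a
non-monotone knot sequence aborts with a pointer at the ROI or photometric
interpretation. Images are expected in MONOCHROME2 convention (more
attenuation = higher grey); the calibration makes all mmAl outputs
invariant under any affine grey transform applied consistently to image
and wedge, which the test suite asserts.

Four sampling circles per bone per compartment, each of diameter `AB/20`
(tibia) or `CD/20` (femur), are placed tangent to the joint line on the
bone side, centered on perpendiculars anchored at the compartment's outer
perpendicular and marching inward at mutual spacing `S/20`. The anchor
keeps the circles inside the same band used for JSW; the paper-level
definition does not fix where the four perpendiculars start, and the
anchor offset is configurable. Pixel membership uses the center-in rule
(pixel center within the radius) so pixel counts are reproducible. The
group value is the mean of its four circle mmAl values.

## JLCA and eminence heights

The JLCA is the angle between L2 and the tibial joint line. Two tibial
definitions are first-class because the field uses both: the framework's
L3 (default) and the clinical line through landmark points 7 and 26; the
report names the one used. The magnitude is `acos(|d2·d3|)`; the sign —
positive when the joint space narrows toward the lateral side — is a
package convention for interpretability (the convention of legacy tools is
not recoverable), and the unsigned value is always reported alongside.
Angles beyond 45° are flagged as implausible, never clamped.

Eminence heights are the perpendicular distances of landmark points 15 and
19 to L3, in mm. Which of the two indices is the medial apex is not fixed
by the shape model, so assignment is by canonical x position (smaller x =
medial) and the rule is recorded in the report.

## The synthetic phantom generator

`phantom_params()`/`generate_phantom()` render a radiograph-like image —
two bone plates whose facing edges realize specified straight joint lines,
a stamped step wedge, optional seeded Gaussian grey noise — and place the
99 landmarks *analytically* on those edges, consistently with the region
map. Geometric ground truth (mean/minimal JSW, JLCA, eminence heights,
per-group mmAl) is therefore closed-form: for two lines meeting at angle
φ, the station-constrained inscribed diameter at a point with
perpendicular gap `d0` is `2·d0/(1 + cos φ)`, evaluated at the same 15
stations per compartment the pipeline uses. The defaults describe a
plausible adult knee at 0.2 mm/px: a 40 mm wide joint, a 5 mm joint
space, eminences 11/13 mm proximal to the plateau, a six-step 2–12 mm
wedge; the 12-phantom suite (`phantom_suite()`) varies tilt, compartment
narrowing, gap, knee width, pixel spacing, noise, laterality and wedge
density. These are the conditions under which the validation suite runs.

What the phantoms deliberately do **not** emulate: curved articular
surfaces, trabecular texture, projection/magnification effects, beam
heterogeneity and scatter, osteophytes, and segmentation failure modes of
the upstream landmark tool. Passing the recovery tests therefore shows the
geometry and calibration engines are correct, not that clinical accuracy
on real radiographs equals phantom accuracy.

`perturb_landmarks()` adds seeded isotropic Gaussian jitter to all 99
points, emulating the difference between checked and unchecked automatic
annotations. Under 0.5 px jitter the validation suite requires mean
signed JSW deltas within 0.15 mm, mean absolute JSW deltas under 0.5 mm,
mean signed JLCA deltas within 0.3°, and mean signed eminence deltas
within 0.15 mm over 100 seeds — thresholds chosen a priori as a
qualitative sanity band, not as a claim about any cohort.

## Numerical choices and degenerate inputs

* Supporting lines: side and touch constraints are enforced to 1e-6 px in
  the property tests; collinear point sets fall back to the line through
  the two extremes.
* Inscribed circles: golden-section tolerance 1e-6 px on the center
  position; validated against an independent dense grid search to 1e-3 px
  on 100 random convex-gap fixtures.
* Parallel border/joint lines (no corner), zero corner distances and
  crossing compartment bands are hard framework errors.
* ICC: the two-way absolute-agreement coefficient is computed from
  explicit mean squares and cross-checked against a `stats::aov` ANOVA
  table to 1e-10; confidence intervals use the F-based construction, with
  the residual-free limit handled analytically (bit-identical runs give
  ICC exactly 1 with a degenerate [1, 1] interval rather than NaN). Zero
  total variance is an error, not NaN.
* Wedge detection requires exactly k contiguous bands after one running-
  median smoothing pass; anything else aborts with instructions to supply
  a manual ROI rather than guessing.

## Problem sizes used by the validation suite

The shipped tests and the acceptance script run entirely on generated
phantoms: a 20-phantom batch (384×384 px, grey noise SD 25) measured twice
for the determinism checks, the 12-phantom suite for ground-truth
recovery, and 100/100/50 randomized fixtures for the geometric and
statistical oracle comparisons. These sizes exercise every code path while
keeping a full run in the low minutes on a single core; all of them are
plain parameters in the test helpers.

## Known limitations

* DICOM files are not read; convert to 16-bit PNG/TIFF and supply pixel
  spacing and laterality in the run configuration.
* The wedge must be axis-aligned stripes with thickness ascending along
  the profile axis in the canonical frame; arbitrary wedge placement or
  rotation requires a manual ROI per acquisition protocol.
* No scatter or heel-effect correction: mmAl equivalence is a relative
  densitometric scale, not bone mineral density.
* Posterior tibial plateau margins are not measured (the anterior margins
  define the joint boundaries), and no whole-limb alignment angles are
  computed.
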