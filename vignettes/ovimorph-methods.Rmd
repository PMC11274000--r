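---
title: "Silhouette morphometry for walking sheep: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Silhouette morphometry for walking sheep: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovimorph)
```

## The measurement problem

Body-size traits of sheep — body slanting length (BSL), withers height (WH),
hip height (HH) and chest depth (CD) — are normally taken by hand on a
restrained, squarely standing animal. ovimorph instead measures them from
side-view binary silhouette masks of sheep walking freely through a capture
channel, where an instance-segmentation model upstream has already isolated
the animal. Free walking means the posture varies: the head may be lowered
or raised, and some animals jump. Posture changes where the anatomical
feature points are found, and jumping makes the skeleton unmeasurable, so
the pipeline first picks a good frame, then classifies posture, then
switches its landmark rules on that posture.

All coordinates are 0-based with x growing rightward and y growing downward;
rectangles are half-open. The package assumes one animal per frame; masks
with several components are reduced to their largest 8-connected component.

## Key-frame screening

A channel pass yields dozens of frames; the measured frame should show the
whole animal centered in view. Each frame is scored by

$$\mathrm{score} = n_1\,|R_1| + n_2\,|R_2| + n_3\,|R_3|,$$

where $|R_i|$ counts mask pixels inside three nested, centered fractional
regions of the frame ($R_1$: central third horizontally, central quarter
vertically; $R_2$: a double-sized margin around it; $R_3$: the full frame)
and $n = (10, 0.5, 0.01)$. A pixel in the center is worth three orders of
magnitude more than one at the border, so clipped or off-center frames lose.
The regions are printed as nested and the decreasing weights already encode
the emphasis, so counting is cumulative by default; an `exclusive` (annular)
switch is provided. The key frame is the arg-max, ties to the earliest
frame. Frames touching the border are not excluded beforehand; the score
already penalizes them.

## Posture recognition

The posture statistic is the acute angle between the diagonal of the
minimum-area (rotated) enclosing rectangle of the contour and the diagonal
of its axis-aligned bounding rectangle, both diagonals taken from the corner
of minimal $x+y$ to the corner of maximal $x+y$. A level walking body scores
near zero; a rising, leg-tucked jumping body opens the angle. Frames whose
angle exceeds a decision-stump threshold of **8.9°** (fitted on real channel
recordings by a one-split decision tree; `fit_jump_stump()` reproduces the
fitting) are labeled `jump`. Otherwise the head point (head-side extreme of
the contour) is compared with the hip point (rearmost convex-hull vertex on
the upper half): head strictly higher gives `head_up`, else `head_down` —
a tie counts as down, the majority class in channel data.

Two constructions of the angle are provided. `diagonal` (default) is the
corner-matched diagonal comparison above; `axis` is the absolute
orientation of the min-area rectangle's long side. For a rigid rectangle
rotated by $\varphi$, `axis` returns exactly $\varphi$ while `diagonal`
responds monotonically but compressed, because the bounding-box diagonal
partially follows the rotation. The corner-matched diagonal pick is not
mirror-symmetric for asymmetric shapes, so `classify_posture()` evaluates
everything in a canonical head-left orientation (mirroring
`head_side = "right"` inputs first); that makes classification exactly
invariant under mirroring with the head side flipped.

## Landmarks and measures

Measures are only taken for walking postures; jump frames are emitted with
blank measures and a `jump_excluded` flag — a mid-jump skeleton is not in a
measurable configuration.

**Body slanting length.** The maximal axis-aligned all-foreground rectangle
of the silhouette is found by the per-row histogram / monotonic-stack
algorithm (linear in the pixel count, implemented in C++; ties broken by
smallest $(y_0, x_0)$ for reproducibility). BSL is the length of its
diagonal, oriented from the head-side lower corner to the rear upper corner.
Rotated inscribed rectangles are out of scope: the stack formulation is
inherently axis-aligned.

**Chest depth.** The straight distance from the withers point to the
head-side *lower* corner of that rectangle, which lies at the sternum's
lower edge on a standing animal — the manual standard defines CD as withers
to sternum. A `cd_corner = "upper"` switch selects the rear-upper-corner
reading instead, since the field description of this endpoint is
orientation-ambiguous.

**Withers and hip, head raised.** The hip is the convex-hull vertex
farthest toward the rear among vertices on the upper half of the
silhouette, ties to the highest. For the withers, line A joins the top of
the head to the shoulder (the head-side end of the inscribed rectangle's
top edge, which on a convex back lies on the outline); the withers is the
contour point of the dorsal arc between those endpoints with maximal
perpendicular distance to line A — the bottom of the neck-to-back dip. A
perfectly straight dorsal line returns the first arc point with a
`flat_dorsal` flag rather than failing.

**Withers and hip, head lowered.** With the head down the scapula and hip
bones protrude from the back line. With $S$ the horizontal extent of the
contour, the withers is searched in the window $[3/8, 4/8]\,S$ and the hip
in $[6/8, 7/8]\,S$, both measured from the head-side boundary (the windows
are listed once each; anatomically the withers sits forward of the hip).
Within a window, restricted to upper-contour points (minimum y per column),
the point maximizing the convex-signed U-chord curvature wins; a window with
no strictly convex point (a flat back) raises a landmark error.

**U-chord curvature.** At contour position $i$, two neighbors $p_{ib}$ and
$p_{if}$ are taken at Euclidean distance $U$ along the contour, walking
backward and forward; with $D = \lVert p_{ib} - p_{if}\rVert$,

$$c_i = s_i \sqrt{\max\!\big(0,\; 1 - D^2/(4U^2)\big)},$$

where $s_i$ is the turn sign of the triple (zero for exactly collinear
points, hence $c = 0$ on straight runs; $|c| \to 1$ at a hairpin). Two
numerical choices matter. First, the radicand uses $4U^2$ *and* the chord
endpoints are placed at exactly distance $U$ by linear interpolation on the
crossing contour segment: snapping to the nearest vertex instead biases
$|c|$ by the sampling density (on a 360-gon of radius 50 px with $U = 10$,
vertex snapping yields 0.096–0.30 depending on normalization, against the
circle's closed-form 0.100, which interpolation reproduces to $2\times
10^{-4}$). Second, $U$ defaults to $\max(5, 0.05\,S)$ px, scaling with the
animal so the chord spans an anatomical prominence rather than pixel noise;
it is configurable because no canonical value exists.

**Heights.** The ground line defaults to the bottom of the lowest
foreground row (hoof contact). WH and HH are the vertical distances from
withers and hip to it. A fixed channel-floor row can be supplied instead
(`ground_mode = "fixed_row"`), which is preferable when a hoof is raised
mid-stride.

## Pixel-to-centimeter conversion

The camera's scale in px/cm depends on where the animal stands. It is
modelled as an additive cubic polynomial in two distances,
$r(u, v) = \beta_0 + \sum_{k=1}^3 a_k u^k + \sum_{k=1}^3 b_k v^k$, fitted by
ordinary least squares to calibration-plate observations taken at 5-cm
steps (side plate 0–50 cm, back plate 0–90 cm). The two published
coefficient sets ship as presets `paper_side` and `paper_back`, used with
their printed signs; evaluation outside the plate range warns, and the back
model's negative value at the origin is exactly such an extrapolation —
`px_to_cm()` therefore refuses non-positive ratios as non-physical.
Centimeter values are pixel values divided by the ratio; the px-per-cm
direction was chosen because plausible channel geometry (u ≈ 20 cm,
v ≈ 150 cm) then gives ≈ 3 px/cm, the right order for a 640-px frame.

```{r}
side <- calibration_preset("paper_side")
eval_ratio(side, 0, 0)      # model value at the coordinate origin
eval_ratio(side, 20, 150)   # a plausible channel geometry
```

## The synthetic testbed

No image data are deposited with the field study, so validation runs on a
parametric generator (`make_silhouette()`) whose ground truth is computed
from the generative geometry only — never by the measurement code, keeping
the oracle independent. A silhouette is the union of a torso ellipse, two
vertical leg slabs (shearing rearward only below the belly line), a neck
band whose dorsal edge sags quadratically into the back (real necks are
concave into the withers; the sag also pins the line-A maximum at the
junction instead of letting it slide along a straight edge), a head disk
with a pointed muzzle wedge, a rump prominence with a pointed rear wedge,
and two upright-elliptical dorsal bumps standing in for the scapula and
hip-bone protrusions. Pointed tips and tight bump apexes make every truth
landmark a *unique* extremum, so localization tolerances are meaningful.
Truth BSL/CD use the closed-form maximal rectangle of the shape union
(the larger of the bare-ellipse rectangle and the leg-to-leg rectangle).

Default proportions emulate an adult sheep at the channel camera's
640 × 480 resolution, about 3 px/cm: torso 290 × 112 px, legs 85 px, neck
115 px. Walking head pitch defaults: −55° lowered (head kept clear of the
ground and of the leg-bottom support line — a head hanging to hoof level
makes the min-area rectangle orientation ill-conditioned), +20° raised.
Jumps are generated as whole-body rotation with the head thrown up at a
fixed +55°, matching how jumping is described in the field: legs bent, head
up.

`sample_channel_params()` draws the population the validation suites use:
posture proportions 65.7 / 16.8 / 17.5 % (head-down / head-up / jump, the
proportions observed on real channel passes), walking tilt half-normal with
3° s.d. truncated at 9° (centered key frames catch mid-stride, level
bodies), jump tilt uniform on 14–24°, anatomy varied ±5 %, 1 px of smooth
boundary noise. Under these conditions the generated rectangle-angle
statistics reproduce the field pattern — walking ≈ 3° with a small spread,
jumps well above the 8.9° stump. A uniform tilt law over [0°, 25°] would
instead place much probability mass exactly at the classifier's geometric
crossover and cap achievable accuracy near 90 % regardless of
implementation quality; sheep do not walk at an 11° body tilt, so that law
was rejected as unrealistic, not merely inconvenient.

What the generator does *not* emulate: wool texture and chest-hair
segmentation errors (a known source of chest-depth error on real animals),
occlusion, motion blur, multi-animal frames, and perspective distortion.
Passing the synthetic suites therefore demonstrates correctness of the
geometry and of the decision logic under controlled conditions, not
field-grade accuracy on real sheep.

## Validation suites and problem sizes

The shipped tests pin every stage to an independent oracle at sizes chosen
to run comfortably on one CPU: the maximal-rectangle kernel against
exhaustive search on 200 random masks up to 16 × 16; U-chord curvature
against the circle closed form (tolerance 10⁻³) on a 360-gon; calibration
fitting against 50 randomly drawn coefficient sets recovered to 10⁻⁶
relative on noiseless grids; posture labels against generator truth on a
200-animal population (≥ 95 % required; the analogous figure reported on
509 real animals is 94.70 %); landmark recovery within 3 px and measure
recovery (median relative error ≤ 5 % for BSL/WH/HH, ≤ 15 % for CD — chest
depth is the weakest measure on real animals too) on 100 level, noise-free
silhouettes; and byte-identical reruns of the full pipeline on a 10-animal
synthetic tree.

## Known limitations

* The posture statistic's diagonal construction responds sub-linearly to
  body rotation; the 8.9° stump is therefore tied to the camera geometry it
  was fitted under and should be refitted (`fit_jump_stump()`) for other
  setups.
* Landmark windows assume the head-side boundary is the nose; a sheep
  looking backward would shift every window.
* The inscribed rectangle is axis-aligned; on a strongly tilted (but
  sub-threshold) body BSL is underestimated.
* Chest depth inherits both withers localization error and the rectangle
  corner, and is structurally the least accurate measure.
* `largest_component()` silently discards all but the biggest blob; two
  overlapping sheep in one mask would be measured as one.
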