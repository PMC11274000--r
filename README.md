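# ovimorph

Posture classification and body-size measurement of sheep walking through a
capture channel, computed from per-frame binary silhouette masks (the output
of an upstream instance-segmentation model). Built for livestock
phenotyping work where restraining every animal for manual measurement is
impractical: the animal walks, the cameras record, and the geometry does
the rest.

The pipeline has four stages:

1. **Key-frame screening** — each frame of a pass is scored by a weighted
   count of mask pixels in three nested, centered regions,
   `score = 10·|R1| + 0.5·|R2| + 0.01·|R3|`, and the best-centered frame
   wins.
2. **Posture recognition** — the acute angle between the diagonal of the
   minimum-area enclosing rectangle and the diagonal of the axis-aligned
   bounding rectangle separates jumping bodies (angle > 8.9°, a
   decision-stump threshold fitted on channel recordings) from walking
   ones; walkers split into head-up vs head-down by comparing the head
   point's height with the hip point's.
3. **Morphometry** — body slanting length (BSL) is the diagonal of the
   maximal inscribed rectangle (per-row histogram + monotonic stack, in
   C++); withers and hip points come from convex-hull and line-distance
   rules when the head is raised, and from U-chord-length curvature maxima
   in the windows `[3/8, 4/8]·S` and `[6/8, 7/8]·S` of the body extent when
   it is lowered; withers height (WH), hip height (HH) and chest depth (CD)
   follow from the landmarks and the ground line. Jump frames are never
   measured.
4. **Calibration** — pixels convert to centimeters through an additive
   cubic polynomial ratio model `r(u, v)` in two camera distances, fitted
   to calibration-plate sweeps; the published side- and back-camera
   coefficient sets ship as presets.

A parametric silhouette generator with exact, independently computed ground
truth (`make_silhouette()`, `sample_channel_params()`) backs the entire
test suite, since no real channel imagery is publicly deposited.

## Worked example

```r
library(ovimorph)

# a synthetic channel pass: 9 frames, head-down walker
seqs <- make_walk_sequence(silhouette_params(head_pitch = -55),
                           n_frames = 9, seed = 7)

kf <- select_key_frame(seqs)
#> key frame: 4   score: 243272.6          # the centered frame wins

mask <- seqs$frames[[kf$frame_index + 1]]$mask
pr <- classify_posture(mask)
#> <posture_result head_down, angle 1.38 deg>   # well under the 8.9 stump

rec <- measure(mask, pr)
#> <measurement_record head_down: BSL 217.5, WH 184.0, HH 181.0, CD 118.1 px>

ratio <- eval_ratio(calibration_preset("paper_side"), u = 20, v = 150)
#> 3.0151                                   # px per cm at that geometry
rec <- apply_calibration(rec, ratio)
#> BSL 72.14 cm, WH 61.03 cm
```

The pixel measures are the four standard traits read off the silhouette:
the inscribed-rectangle diagonal (slant body length), the vertical drops
from the withers and hip landmarks to the hoof line, and the
withers-to-sternum distance. Dividing by the calibrated px/cm ratio at the
animal's standing position gives centimeters.

Whole dataset trees (`<root>/<ear_tag>/<view>/<frame>.png`) are processed
with `run_pipeline(root, pipeline_config())`, which writes the standard
13-column measurement CSV, flags jumping animals as `jump_excluded`, and
logs per-animal failures without aborting the run. A thin command-line
wrapper with the same verbs lives in `inst/cli/ovimorph`.

## Testing

```sh
Rscript -e 'devtools::test()'
```

The suite checks every geometric primitive against an independent oracle
(exhaustive rectangle search, circle closed forms, per-pixel region
counts), and validates the full pipeline on fixed-seed synthetic
populations with known landmark truth. See the methods vignette
(`vignettes/ovimorph-methods.Rmd`) for the models, parameter choices and
the generator's design.

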