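---
title: "Digitizing handwritten anesthesia charts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digitizing handwritten anesthesia charts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chartdigitizer)
```

## The problem

A paper anesthesia record packs several encodings onto one sheet: blood
pressure as paired arrow glyphs on a 5-minute grid (downward = systolic,
upward = diastolic, y in mmHg with one printed line per 10 mmHg),
physiological indicators as handwritten digit strings free to drift along
the time axis of their labeled row, and procedural booleans as checkbox
columns. A smartphone photograph of that sheet adds perspective distortion,
shadows, and blur. This package implements the geometric and photometric
normalization and all the rule-based inference that turns detector output
(bounding boxes) into a structured record. The learned detectors themselves
are deliberately outside the package core: every algorithm here consumes
only "a list of labeled boxes" or "a digit label", which is exactly the
interface a trained single-class object detector and digit classifier
provide. Deterministic fixture implementations of those contracts make the
whole chain testable.

## Photometric normalization

Shadows are removed by estimating the illumination background with a
grayscale dilation (a running maximum, which erases thin dark ink strokes)
followed by a median blur, then taking the absolute pixel-wise difference
between image and background, inverting so ink is dark on a light page, and
min-max rescaling to [0, 255].

Tunables: `dilate_kernel` (px, odd; default 7 at a 1000 px working width)
must exceed the stroke width so ink vanishes from the background estimate;
`blur_kernel` (px, odd; default 21) sets the smoothness of the illumination
model and must be at least the dilation kernel. Both scale linearly with
image width via `scale_shadow_params()` because stroke width scales with
resolution. A constant image normalizes to all-255 (blank paper), the
documented degenerate case. The inverted-difference variant is the default
because chart ink is dark on white; the raw difference is available with
`invert = FALSE`. No scalar "shadow quality" metric is computed in the
pipeline; the tests instead measure background standard deviation and
foreground/background contrast on constructed gradient fixtures, where both
are exactly known.

One caveat discovered while calibrating the tests: the background estimate
lags a linear gradient by roughly the dilation radius times the gradient
slope, so on a very narrow image with a steep gradient the residual offset
approaches the 2-intensity-level idempotence tolerance. At realistic chart
resolutions (several hundred px across a gradient) the residual is well
under one level.

## Geometric normalization

Four printed landmarks ("Total", "Time", "Procedure Details", "Patient
Position") sit in the chart corners. With exactly four named
correspondences the planar homography is solved exactly by the direct
linear transform (an 8×8 linear system); there is nothing to estimate
robustly, so failure modes (a landmark obscured, covered, or out of frame)
are surfaced as errors naming the missing landmark rather than worked
around. The correspondence point of a detected landmark is its box center —
which pixel of the landmark the correspondence should anchor is genuinely
open, and the center is the only choice that is symmetric under the box
jitter a detector produces. Warping resamples bilinearly; out-of-source
pixels fill white. Feature-matching alternatives (ORB/SIFT) are
deliberately not implemented: on low-quality photographs they fail
silently, which is worse than failing loudly.

Section positions come from the layout configuration after warping. The
layout (`chart_layout`, YAML) is configuration rather than code so a
different hospital's chart needs a new file, not a new package. The real
chart's pixel geometry is not published anywhere; the bundled
`chuk_layout()` is a structurally faithful stand-in (1000×700 reference
frame, seven sections, 1 mmHg/px blood-pressure grid), and the package
makes no claim of coordinate-level fidelity to any specific hospital's
form.

## Tiling and duplicate merging

Handwritten symbols are small relative to the sheet, so detection runs on
overlapping tiles: a sliding window advancing by half its width/height,
with the final row/column clamped to the image edge. The clamping (rather
than padding) guarantees every tile pixel is a real image pixel and every
object no larger than the stride is fully contained in at least one tile.
The cost is duplicated detections, which are merged by grouping same-label
boxes whose IoU exceeds a threshold into connected components (union-find)
and replacing each component with the score-weighted mean box (max-score
selection is available). `iou_threshold` defaults to 0.4: chart symbols are
well separated and never overlap, so duplicates of one glyph have high IoU
while distinct neighbors have IoU near zero, and any moderate threshold
separates the two regimes. Idempotence of merging holds in that
well-separated regime (and is tested there); in dense random box soups a
merged representative can overlap a neighboring component, which is outside
the operating conditions of this chart.

## Blood pressure

Down- and up-arrows are vertical mirror images, so one single-class
detector suffices: it runs on the section for systolic marks and on the
vertically flipped section for diastolic marks, whose y-centers are then
restored as `height − y`. Interpolation anchors on the printed "200" and
"30" legend markers: the span between their box centers covers 170 mmHg,
giving a linear y→mmHg map. Values are read at the arrow's box center; with
vertically symmetric arrow glyphs the tip offset cancels, and a
configurable `tip_offset` exists for asymmetric glyph sets. Values beyond
the printed [30, 200] span extrapolate linearly and are flagged rather than
clipped.

Timestamps use only relative x-geometry. Systolic/diastolic boxes within
1% of the section width pair greedily (globally closest first, each box
used once, ties toward the leftmost); unpaired boxes become one-sided
readings. Reading-to-reading spacing within 1.8% of the width advances the
clock 5 minutes, larger spacing 10 minutes — the observed spacing of true
consecutive pairs stays within 1.6% of the width, and 1.8% adds margin.
Two open choices were resolved as follows: the series origin is t = 0 at
the first reading (only relative timing is recoverable from geometry), and
a gap of two or more missed epochs still advances 10 minutes, since the
spacing rule cannot distinguish longer gaps; the synthetic generator
therefore skips at most one epoch at a time so that ground-truth timing
stays within what the rule can express.

## Physiology

Processing order: detect digits → assign rows → cluster observations →
classify → assemble → filter → impute.

Row assignment clusters digit y-centers with k ∈ 2…7 chosen by maximum
silhouette. If the y spread is small (below a quarter of the narrowest row
band — "a few pixels" made concrete) or fewer than three digits exist, a
single cluster is used; silhouette is undefined at k = 1 and k = n, so
those arise only via these explicit special cases. Each cluster goes to the
row whose y-band contains its centroid; a centroid in no band discards the
cluster with a warning recorded in provenance. The 1-D k-means itself is
solved exactly by dynamic programming over split points (optimal 1-D
clusters are contiguous in sorted order), so clustering is deterministic
with no initialization or empty-cluster pathologies. The silhouette is
computed in-package with explicit degenerate-case policy (singleton
clusters and zero-distance ties score 0) and is cross-checked in the tests
against both a loop-based brute-force implementation and
`cluster::silhouette`.

Observation clustering on x-centers searches k in
[⌊n/d_max⌋ − ⌈0.1n⌉, ⌈n/d_min⌉ + ⌈0.1n⌉], clipped to [1, n], where
d_min/d_max are the row's plausible digits per value (SpO2: 2–3) and the
10% margin absorbs missed and spurious boxes. The tidal-volume row writes
"TVxRR"; its cluster is split at the "X" glyph identified by the
classifier's one-vs-rest `x_mark()`, falling back to a last-two-digits
split (tidal volume is nearly always three digits, respiratory rate two)
when no X is found. The respiratory-rate row spec exists only to supply
ranges for the right half of that split; its y-band is an unused disjoint
placeholder, since the digits physically sit on the tidal-volume line.

Plausibility filtering runs two rules in order. Range: outside the row's
plausible values (SpO2 ∈ [75, 100], EtCO2 ∈ [15, 60], FiO2 ∈ [21, 100],
tidal volume ∈ [200, 800] mL, respiratory rate ∈ [5, 40] /min). Step: a
one-sided tolerance on successive differences (defaults per epoch: SpO2 5,
EtCO2 10, FiO2 20, tidal volume 150, respiratory rate 5 — configuration
values, since the tolerance would properly be fit to each site's data). The
step rule is applied by iterative consensus: a value qualifies as an
outlier only if *all* of its available range-plausible, unflagged neighbors
differ from it by more than the tolerance, and the most deviant qualifying
value is flagged first, then neighbors recomputed. A literal "either
neighbor differs" rule would also flag the correct values adjacent to a
single misread (in the canonical scenario 98, 79, 100 with true value 99,
the 98 sits 19 from the 79); the consensus rule flags exactly the 79.

Imputation fits ordinary least squares on (index, value) of up to the two
previous and two next plausible values (at least two required, else the
value stays flagged), predicts at the flagged index, rounds half away from
zero, and clips into the row's range. Neighbors are always
originally-plausible values: imputed values never feed later imputations,
so one misread cannot cascade. At series boundaries whatever plausible
neighbors exist inside the ±2 window are used, down to a two-point line.

The error metric for physiological rows matches lists index-wise,
truncating the longer list to the shorter — e.g. (99, 98, 97) against
(98, 99, 100) scores (1 + 1 + 3)/3 = 5/3.

## Checkboxes

Labels are assigned purely geometrically: sort all detections by x-center,
take the first c₁ for the leftmost column, sort those by y-center, zip with
the column's labels, repeat. This presumes a complete detection set, so a
count mismatch is a hard error by default — on real sheets this trades a
minority of rejected sheets for near-perfect label inference on the rest. A
lenient mode (`strict = FALSE`) exists as a clearly-marked extension. The
sequential-take rule is implemented verbatim and shares its known
fragility: two columns with nearly identical x-centers under heavy jitter
could interleave; the bundled layout keeps 85 px between columns, and the
tests jitter up to ±10 px.

## The synthetic generator and what passing tests mean

`render_chart()` draws a simplified chart in the reference frame from a
deterministic built-in stroke-glyph set (no handwriting samples, no
downloads): grid lines, the "200"/"30" legend, arrows at exact mmHg
positions on a 1 mmHg/px grid, digit rows with ±2 px seeded jitter, "TVxRR"
with a real X glyph, checkbox squares with check strokes, and the four
corner landmarks, every glyph paired with exactly one ground-truth box.
`distort()` applies a seeded inward perspective warp (the page stays a
convex quad in frame, as when photographing at an angle), an additive
illumination gradient, and optional blur, recording the exact homography.
The default sheet density — 17 blood-pressure epochs and 34 physiological
datapoints (8 + 8 + 8 values on the three digit rows plus 5 "TVxRR" pairs)
— mirrors the roughly 35 datapoints per synthetic evaluation sheet used
when such pipelines are assessed under best-case handwriting.

Values are generated as seeded random walks inside realistic adult ranges
(systolic around 120, diastolic about 40 mmHg lower, SpO2 90–100, EtCO2
25–55, FiO2 30–100, tidal volume 350–650 mL, respiratory rate 10–20).

What the generator does *not* emulate is exactly the part held behind the
detector contracts: handwriting variability, ink weight, paper texture,
lens blur beyond a Gaussian, and real detector/classifier error
distributions. Passing the zero-noise end-to-end test therefore certifies
the correctness of the geometry and inference chain, not real-photograph
accuracy; the fixture noise model (center jitter, false negatives/positives
at configurable rates, a digit confusion matrix) lets the degradation of
each stage be studied, but its error rates are inputs, not measurements.

## Numerical choices

- Coordinates are continuous pixels, origin top-left, y downward, boxes
  stored center+size; one convention across all modules.
- Glyph stamping rounds half up (base R rounds half to even, which would
  shift glyph centers by ±0.5 px depending on parity); legend digits use an
  odd scaled height so their centers land exactly on integer targets.
- The DLT solves an 8×8 system directly; configurations with three
  collinear landmarks are rejected by a triangle-area test at 1e-9.
- Silhouette comparisons use a 1e-12 slack when maximizing over k so exact
  ties resolve to the smaller k deterministically.
- systolic > diastolic is *not* enforced on readings: a violated ordering
  indicates a detector fault worth surfacing, and silently swapping values
  would hide it.
- Sheet-level problem sizes in the tests and the acceptance script (500
  random quads, 200 clustering rows, 100 checkbox layouts, 600 jittered
  arrows, one full end-to-end sheet per configuration) were chosen so each
  property is measured at a few hundred independent draws.

## Known limitations

- Only planar perspective is corrected; page curl and lens distortion are
  out of scope, consistent with anchoring all downstream rules on relative
  geometry rather than exact pixels.
- Heart-rate dots/lines, free-text sections (medications, fluids,
  transfusions), and volatile-agent rows are not digitized.
- The layout ships with plausible, not measured, CHUK geometry; deploying
  at a real site means measuring a scanned control sheet once and writing
  its YAML.
- The strict checkbox count guard rejects whole sections on a single
  missed detection; that is a deliberate precision/coverage trade.
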