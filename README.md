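# chartdigitizer

Turns smartphone photographs of handwritten paper anesthesia charts into
structured, machine-readable records.

In many low- and middle-income hospitals, the intraoperative anesthesia
record is a single sheet of paper: blood pressure charted as downward
(systolic) and upward (diastolic) arrows on a 5-minute grid in mmHg,
physiological indicators (SpO2, EtCO2, FiO2, tidal volume "TVxRR") written
as free-floating digit strings on labeled rows, and procedural booleans as
checkbox columns. This package implements the computer-vision
post-processing that converts a photograph of such a chart into numbers, for
researchers and quality-improvement teams who need digital access to that
data without electronic medical record infrastructure.

## What it does

The pipeline is: grayscale conversion → morphological shadow removal
(background = median-blur(dilate(image)), subtracted and renormalized) →
detection of the four printed corner landmarks → exact four-point planar
homography *H* (direct linear transform) warping the photo into a reference
"control chart" frame → section cropping → half-stride sliding-window tiling
for small-object detection with intersection-over-union duplicate merging →
per-section inference:

- **Blood pressure** — a single one-class arrow detector is run on the
  section and on its vertical mirror (down- and up-arrows are reflections);
  the "200" and "30" printed legend markers anchor a linear y→mmHg map,
  `mmHg(y) = 200 − (y − y₂₀₀)·170/(y₃₀ − y₂₀₀)`; timestamps are imputed from
  relative x-distances (systolic/diastolic pairs within 1% of the section
  width; a step of 10 min instead of 5 when consecutive readings are more
  than 1.8% of the width apart).
- **Physiology** — digit boxes are assigned to rows by 1-D k-means on
  y-centers (k ∈ 2…7, silhouette-maximal), clustered into multi-digit
  observations by 1-D k-means on x-centers with
  k ∈ [⌊n/d_max⌋ − ⌈0.1n⌉, ⌈n/d_min⌉ + ⌈0.1n⌉], classified, and
  concatenated. Values outside a row's plausible range (e.g. SpO2 ∉
  [75, 100]) or jumping more than a per-row tolerance against both neighbors
  are flagged and re-imputed from a local least-squares line through up to
  the two previous and two next plausible values.
- **Checkboxes** — detections sorted by x-center, taken column by column,
  sorted by y-center, zipped with the layout's labels; a detection count
  different from the layout's expected count is a hard error (reject the
  sheet rather than misalign every label).

Learned components (the object detectors, the digit classifier) sit behind
pluggable contracts. The package ships deterministic fixture implementations
and a synthetic-chart generator with exact ground truth, so the entire
post-processing chain is testable without clinical data or model weights;
real detector adapters can be plugged in through the same contracts.

## Worked example

Render a synthetic chart, photograph it (perspective warp + shadow
gradient), and digitize the photo:

```r
library(chartdigitizer)

layout <- chuk_layout()                      # bundled reference geometry
spec <- synth_spec(layout, seed = 42,
                   distortion = distortion_spec(corner_shift_frac = 0.03,
                                                shadow_gradient = 60))
photo <- distort(render_chart(spec))

landmarks <- as_photo_frame(photo$truth)$landmarks   # what a detector sees
detectors <- fixture_detectors(photo$truth, landmark_truth = landmarks)
record <- digitize(photo$image, layout, detectors, seed = 42)
record
#> <digitized_record>
#>   blood pressure: 17 reading(s)
#>   physiology:     34 value(s) in 5 row(s)
#>   checkboxes:     13/16 checked

head(record$bp, 4)
#> # A tibble: 4 × 3
#>   t_minutes systolic diastolic
#>       <dbl>    <dbl>     <dbl>
#> 1         0      120        83
#> 2         5      116        75
#> 3        10      104        57
#> 4        20      115        75
```

The third→fourth reading jumps 10 minutes: the generator skipped an epoch
there and the timestamp rule recovered it. Scoring against the generator's
ground truth:

```r
evaluate(record, photo$truth)$bp
#> # A tibble: 1 × 4
#>   systolic_mae diastolic_mae n_systolic n_diastolic
#>          <dbl>         <dbl>      <int>       <int>
#> 1            0             0         17          17
```

With noise-free fixtures the distorted chart is recovered exactly; MAE rises
once detector jitter, drops, or digit confusion are switched on via
`fixture_noise()`. `tidy(record)` gives one long tibble of every extracted
value, `glance(record)` a one-row summary, and `autoplot(record)` the
blood-pressure series.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/chartdigitizer.R synth --seed 11 --out fx
Rscript inst/cli/chartdigitizer.R digitize --image fx/chart.png \
    --layout inst/extdata/chuk_layout.yaml --detector fixture:fx \
    --no-homography --out record.json
Rscript inst/cli/chartdigitizer.R evaluate --record record.json \
    --truth fx/truth.json
```

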