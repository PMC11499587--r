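---
title: "Plot-grid segmentation and panicle phenotyping: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plot-grid segmentation and panicle phenotyping: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldplotr)
```

## The problem

Rice breeding trials plant hundreds of rectangular micro-plots in a regular
grid. A UAV flying 15 m above the field produces an orthomosaic at a ground
sample distance (GSD) of about 1.9 mm/pixel, from which breeders want, per
plot and per acquisition date: the plot boundary, the growth stage, the
panicle number per unit area (PNpA, panicles/m²), and a panicle-curvature
class. `fieldplotr` implements the full geometric pipeline around a
pluggable instance detector, plus every evaluation statistic the workflow
reports. Trained network weights and the original field imagery are not
part of the package; a synthetic field simulator stands in so that every
stage is testable.

## The grid-segmentation procedure

The core algorithm converts per-tile plot detections into a complete plot
grid:

1. **Orientation.** The mosaic's dominant grid angle is estimated from the
   excess-green index ($ExG = 2G - R - B$), Otsu thresholding, and the
   circular median (mod 90°) of nearest-neighbor direction angles between
   vegetated-component centroids, folded into $(-45°, 45°]$. The mosaic is
   rotated to axis alignment about its center, with canvas expansion and an
   accumulated affine transform so no coordinate information is lost.
2. **Tiling.** The rotated mosaic is cut into 1600 × 1600 px tiles with a
   1/4 overlap of the tile *side* (stride 1200). The final tile per axis is
   anchored flush to the image edge, so coverage is complete and every tile
   is full-size whenever the mosaic permits. We read the ambiguous "1/4
   overlap" as a side fraction; an area fraction would imply stride ≈ 1386.
3. **Detection.** Any function `(tile) -> detection_set` may be plugged in:
   the COCO adapters ingest externally produced detections, and
   `detect_plots_baseline()` provides a classical fallback (ExG → Otsu →
   closing/opening with a square element of about the plant spacing → hole
   filling → connected components). Its scores are deterministic area
   ratios, not confidences, so `segment_plots()` applies no score threshold
   by default; the 0.5 default documented for the config file is meant for
   external scored detectors.
4. **Merging.** Detections from overlapping tiles are merged when their
   overlap exceeds 60%. Overlap is measured as intersection over the
   *smaller* area by default: a tile-boundary fragment of a plot is almost
   fully contained in the whole-plot detection, which containment captures
   but IoU does not. Masks are used when both instances carry them, else
   boxes. Each connected component of the overlap graph collapses to one
   instance (mask union, bounding box of the union, maximum score); the
   result is independent of input order.
5. **Line fitting and completion.** Merged centroids are clustered 1-D into
   rows (by y) and columns (by x): sort, estimate the pitch as the median
   of consecutive differences larger than a quarter of the *maximum*
   difference, and split at gaps above half the pitch. (Anchoring the
   restriction to the maximum rather than the median difference matters
   once groups have many members, because the median consecutive difference
   is then within-row jitter, not pitch.) Ordinary least squares gives row
   lines $y = ax + b$ and column lines $x = ay + b$; singleton groups get
   axis-parallel lines. Row × column intersections are the cell centers. A
   merged detection claims the nearest cell within half the smaller mean
   plot dimension (nearest pairs first, one cell per detection); unclaimed
   cells are *completed* with mean-size boundaries, where the mean is over
   the claiming detections. Detected cells keep their own boxes by default;
   `uniform_boundaries = TRUE` gives every cell the mean-size box, since
   the source description admits both readings.

## Growth staging

Each plot has a calendar: the full-heading day (`fhs_day`, 80% of panicles
headed) and the maturity day (`ms_day`). The full-heading-to-maturity
interval (FHtM) is split into thirds with half-open left-closed boundaries;
`ms_day` itself closes the final third. Acquisitions before heading or
after maturity are flagged and excluded from panicle datasets. The
canonical example — heading at day 90, maturity at day 120 — places day 98
in the first third, 104 in the second, 111 in the final, and excludes 125.
Boundary conventions are declared, not inferred: the worked example never
touches a boundary. Calendars are per-plot; a population-average calendar
can be emulated by passing the same values for every plot.

`heading_duration()` computes the day-span between 10% and 80% heading from
a ratio time series, after a running-maximum cleanup (heading is
cumulative, so observed dips are measurement noise) and linear
interpolation between bracketing observations.

## Panicle quantification and angle classes

PNpA from imagery is `count / (crop_px × gsd / 1000)²` over a square crop
centered on the plot (700 px for the large-plot layout, 400 px for the
small). The traditional estimator samples `k = 6` plants without
replacement, averages their panicle counts, and multiplies by the planting
density (25 plants/m² at 20 cm spacing; ≈ 59 at 13 cm). Density scaling is
used rather than plot-area division; both readings are noted in the ledger
of open questions.

Panicle curvature uses four classes at 0°, 15°, 45° and 90° from vertical.
Class assignment is nearest-center with bin edges at the midpoints (7.5°,
30°, 67.5°), edges assigning upward. The plot-level class is the mode, ties
breaking toward the larger (more curved) angle. Training an image
classifier for these labels is out of scope; classes come from synthetic
truth or external per-panicle predictions.

## Evaluation suite

All the workflow's statistics are implemented and unit-tested against
independent oracles:

* Euclidean centroid distance and IoU (×100 when reported as %);
* greedy score-ordered detection matching (verified to equal brute-force
  optimal matching in TP count on ≤ 5-box cases);
* AP as the area under the all-point precision envelope (verified against
  1e-6 midpoint Riemann integration) and AR as the mean recall over the
  stated IoU thresholds, with an optional detection budget;
* R², RMSE, rRMSE (% of the observed mean); accuracy and one-vs-rest
  precision/recall/F1 from a confusion matrix;
* relative improvement `100 (new − base) / base`, exercised against the
  shipped detector benchmark table;
* the sampling-stability report (means, n−1 SDs, two-sided rank-sum test
  with normal approximation, Pearson correlation).

The AP interpolation choice (all-point vs 11-point) is switchable because
the source protocol is unstated; all-point is the default and the tested
path. AR defaults to an unlimited detection budget for the same reason.

## The synthetic field: what it does and does not emulate

`generate_field()` renders plots as filled rectangles with per-pixel hue
noise on a dark soil background, with stage-dependent appearance: green
canopy in the first third, green with bright speckles (emerging panicles)
in the second, yellow-brown with golden speckles in the final third.
Panicles are Poisson-distributed per plot (default density 300/m², a
typical paddy value at heading, consistent with reported plot means around
270–310/m²) and rendered as small oriented blobs; their orientation encodes
the angle class for visual sanity only. Calendars are drawn uniformly
(heading 85–95 d, maturity 25–35 d later) so one simulated campaign spans
all three thirds. Truth is generated separately from rendering
(`generate_field_truth()`), so statistical tests over hundreds of plots
never touch pixels, and everything is bit-reproducible from `(config,
seed)` through named RNG substreams.

The simulator makes no attempt at radiometric realism, stitching artifacts,
occlusion, lodging, or within-plot heading variation. A green end-to-end
test therefore establishes that the *geometry* pipeline — orientation,
tiling, merging, line fitting, completion, coordinate bookkeeping — is
correct under jitter and dropout; it says nothing about detector quality on
real canopies, which is exactly the part the package leaves pluggable.

## Numerical choices and degenerate inputs

* Pixels are 0-based, origin top-left, boxes half-open on max edges; one
  global convention avoids off-by-one drift across modules.
* Rotation uses inverse-mapped bilinear interpolation; a rotate/unrotate
  round trip moves interior points by well under a pixel.
* The end-to-end benchmark (10 × 10 plots of 2.4 m × 2 m, 0.4 m gaps, 5°
  rotation, 3 px jitter, 10% detection dropout, seeds 1–10) renders at
  10 mm/px: the same geometry at the flight GSD of 1.9 mm/px would need a
  ~186-megapixel mosaic, which desk-scale tests cannot afford. Dropout is
  injected as a seeded deletion of exactly 10% of *merged* detections,
  emulating per-plot detector misses (per-tile deletion would be mostly
  healed by overlapping tiles before grid fitting).
* Degenerate inputs raise tagged errors: fewer than 4 centers
  (`insufficient grid`), parallel line pairs (`grid undetermined`),
  heading series that never reach 80% (`incomplete heading`), zero-variance
  samples for correlation, zero base for relative improvement. Pipeline
  stages wrap errors with their stage name.
* Raster I/O uses portable PNM (P6/P3): the offline toolchain has no
  PNG/TIFF codec, and the pipeline itself only needs arrays.

## Known limitations

Single rectangular grids only (no multi-block trials, no perspective
correction); no mosaicking from raw frames; no detector training; angle
classes are bookkeeping for external predictions; heading-duration needs
observation series that bracket both 10% and 80% heading.
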