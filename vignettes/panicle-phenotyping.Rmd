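---
title: "From aerial plot images to heading-date traits: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From aerial plot images to heading-date traits: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panicleR)
```

panicleR implements the image-analysis half of a drone-based rice
phenotyping workflow: each aerial frame, acquired centered on one field
plot, is reduced to a single panicle count, and the per-plot counts over a
season of flights become growth curves from which heading-date traits are
read off. This vignette explains the model behind each stage, the tunable
parameters, the design choices made where conventions were open, and what
the synthetic fixtures do and do not establish about real imagery.

## Plot locating

A frame covers more ground than the plot of interest, so the first step
isolates a fixed-size window containing the central plot.

**Vegetation index.** Every pixel is scored with the color index of
vegetation extraction,

$$\mathrm{CIVE} = 0.441\,R - 0.811\,G + 0.385\,B + 18.78754,$$

whose dominant negative green coefficient makes foliage pixels strongly
negative while soil stays positive. `compute_cive()` is linear in the pixel,
so the map inherits the image's noise structure unchanged.

**Binarization.** Otsu's method needs a histogram; CIVE is continuous. The
map is affinely rescaled so min maps to bin 0 and max to bin 255, the
256-bin split maximizing between-class variance is found, and the threshold
is mapped back to CIVE units as the upper edge of the optimal bin — which
makes the vegetation mask the exact level-set
$\{\mathrm{CIVE} \le \tau\}$ of the reported threshold $\tau$. Vegetation is
the *low* side because green minimizes the index. A constant map has no
separable classes and is returned as an all-false mask with a degeneracy
flag rather than an arbitrary split.

**Minimum-boundary search.** Vegetation pixels are counted per row and per
column, each profile is smoothed with a moving average (window 100 px by
default), and the window origin minimizes

$$\mathrm{smoothed}[i] + \mathrm{smoothed}[i + h - 1]$$

over all feasible placements (independently per axis, with window height
$h$ and width $w$): plot boundaries fall in the low-vegetation gaps between
plots, so the correct placement puts both boundary lines in profile dips.
Three conventions here are deliberate choices, recorded in the
configuration:

* the second boundary index is $i + h - 1$, so both boundary rows lie
  *inside* an exactly $h$-row window and the search stays in bounds;
* the moving average is centered with edge windows truncated to the valid
  range — a trailing window would shift every boundary by half a window;
* tied minima return the median index of the tied run, so degenerate
  profiles (all-equal, e.g. an all-vegetation frame) fall back to the
  centered placement, which matches how the frames are acquired.

An even smoothing window cannot be perfectly centered; its half-pixel
asymmetry means the located origin can sit one pixel off the geometric
optimum of the unsmoothed scene. On the synthetic scenes this shows up as a
constant 1 px offset per axis (window IoU 0.989 against truth); that is the
resolution limit of the method, not noise.

The default window is 3800 × 2000 px, the expected extent of a 2 × 1.1 m
plot at the reference flight altitude and zoom. The cm→px factor depends on
the camera geometry, so the window size is a user parameter, not a derived
quantity. Coordinates throughout the package are 0-based with half-open
windows $[r_0, r_0+h) \times [c_0, c_0+w)$, matching the COCO/YOLO box
conventions used at the detection stage.

## Tiled detection and merging

Panicles are small relative to a plot image, so detection runs on
1000 × 1000 px tiles. For prediction the tiles overlap by a ratio of 0.25:
stride $= \mathrm{round}(\mathrm{tile}\times(1-\mathrm{overlap}))$, offsets
$0, s, 2s, \dots$, and the final offset is clamped to `extent - tile` so the
last tile aligns with the image edge. Clamping (rather than padding) avoids
synthetic border pixels that would perturb detections; it also covers the
trailing band that a plain stride-1000 annotation tiling of a 3800-px-wide
plot would miss. A 3800 × 2000 plot yields 15 tiles.

The detector itself is pluggable (`detector_backend()`): anything that maps
a tile to scored boxes satisfies the contract, including detections
pre-computed by a trained network and loaded from COCO-JSON or YOLO files.
The backend is responsible for its own internal deduplication (the
convention for the trained networks this package is designed around is NMS
at IoU 0.5 with validation score threshold 0.05); this module applies only
the *cross-tile* merge: lift each tile's boxes to plot coordinates, drop
boxes scoring below 0.3, and run greedy NMS at IoU 0.25. The confidence
filter runs before NMS — filtering first is order-safe and cheaper. Greedy
NMS keeps the highest-scoring box and discards overlapping rivals; score
ties break to the larger box, then input order, and the merge stage sorts
the pooled boxes canonically first so the result is independent of tile
order. The panicle count of a plot is the cardinality of the merged set.

The reference blob detector used for testing thresholds mean-RGB brightness
and emits one box per connected component within an area range. It drops
components touching the tile border: with 25% overlap every panicle smaller
than the overlap appears whole in some tile, and keeping truncated
fragments would seed duplicates that sit below the merge IoU.

## Evaluation metrics

Counting quality uses RMSE and $R^2 = 1 - SS_{res}/SS_{tot}$ over per-image
(manual, predicted) count pairs; $R^2$ can legitimately be negative for a
predictor worse than the mean. Detection quality uses precision/recall
matching at an IoU threshold $k$ — predictions in descending score order,
each matched at most once to the unmatched ground truth of highest IoU,
ties to the lower index — and average precision
$AP@k = \int_0^1 P(R)\,dR$ evaluated with 101-point interpolation
(precision at recall $r$ taken as the maximum precision at recall $\ge r$),
the convention of the COCO benchmark family this metric names.
`map_50_95()` averages AP over the ten thresholds $0.50, 0.55, \dots,
0.95$; the divisor is exposed as an argument for compatibility with
normalizations over nine, but the ten-threshold mean is the default and the
standard reading.

## Growth curves and heading-date traits

After counting, each plot contributes a growth curve of (date, count)
points. Six traits are extracted. The maximum panicle count is the raw
per-curve maximum $M$. For a fraction $y \in \{0.1, 0.3, 0.5, 0.8\}$ the
heading date is

$$\mathrm{hd}_y = \arg\min_x\,\bigl|c(x) - y\,M\bigr|,$$

the observed flight date whose count is closest to $y\,M$, with ties to the
earliest date (a stage is "reached" at first attainment). The heading stage
is $\mathrm{hd}_{0.8} - \mathrm{hd}_{0.1}$ in days. The argmin runs over
observed dates only — no interpolation — so trait resolution is bounded by
the flight cadence; daily flights give day resolution. Dates are handled
internally as integer day offsets from the first flight; ISO dates are
accepted at I/O and returned in kind. An optional running-maximum
preprocessing (`monotonize = TRUE`) suppresses transient count dips from
detection noise but is off by default: the raw formula is the primary
definition, and monotonizing changes none of the systematic behaviors
discussed below.

## Synthetic fixtures: what they emulate and what they prove

`generate_field_scene()` renders a soil background, vegetation everywhere
except low-vegetation gap bands, and bright elliptical panicle blobs at
recorded positions, all as a pure function of a seed. The gap bands are
centered on the true window boundary — vegetation stops half a gap inside
the window and resumes half a gap outside, where neighbouring plots begin.
That geometry is exactly what the locator's objective models: both boundary
lines of the correct placement sit in profile minima simultaneously. Blobs
keep a minimum clearance (default 20 px) from each other and from the plot
border, so the reference detector sees disjoint components and every blob
survives the tile border rule.

`generate_series()` simulates a count series as a logistic curve
$c(t) = K/(1+e^{-r(t-t_0)})$ observed daily over 42 flights with additive
Gaussian noise (standard deviation $\sigma$), rounded to non-negative
integers. The analytic heading date at fraction $f$ is the quantile
crossing $t_0 + \log(f/(1-f))/r$, and the analytic heading stage is
$\log 36 / r$ — independent of $K$ and $t_0$. Defaults ($K = 120$,
$r = 0.35$, $t_0 = 20$) give a plot reaching ~120 panicles with a ~10-day
heading stage, the shape of a typical season.

These fixtures establish *pipeline correctness* — that each stage computes
its stated function — not performance on real imagery. Real aerial frames
have occlusion, panicle/foliage color overlap, perspective and illumination
variation; none of that is modeled, and a trained detector filling the
backend contract is responsible for it. Passing the synthetic suite says
the plumbing around such a detector is exact.

## Numerical behavior of trait extraction under noise

Because the fixtures carry analytic truth, the package can quantify its own
trait-extraction error (the acceptance script in `scripts/` recomputes
this). Noiseless logistic series recover the 50% heading date exactly. With
count noise at 3% of $K$, the 50% date stays within ±1 day in ~98% of
simulated seasons, but the 10% and 80% dates degrade to ~67% and ~71%
within ±1 day, and the heading stage is within 2 days of $\log 36/r$ in
only ~73%. Two structural effects cause this, and both are properties of
the trait definition rather than of the implementation:

* $M$ is the maximum of ~15 plateau observations, so noise inflates it by
  roughly $1.7\sigma$ (extreme-value bias). The targets $0.1M$ and $0.8M$
  shift accordingly; at the 80% crossing the curve's slope is only
  $K r f(1-f) \approx 0.16\,K r$ per day, so the shift translates into most
  of a day of bias before argmin jitter is added.
* At early dates the expected count is near zero, so a single noisy
  observation occasionally lands closer to $0.1M$ than the true crossing's
  own noisy count does, and the earliest-date tie-break locks it in.

The 50% date is robust because the logistic slope peaks there and the
target $0.5M$ moves only half as much as $M$. Users comparing heading dates
across genotypes should prefer hd50 when counts are noisy, or smooth counts
upstream; monotonizing does not remove the maximum-inflation bias.

## Problem sizes and defaults

The package's tests and the acceptance script run the full pipeline on
scenes scaled to a 600 × 800 px frame with a 300 × 420 px plot, a 40 px
gap, 200 px tiles and a 30 px smoothing window — the same geometry as the
full-size configuration (gap ≈ 13% of plot height, smoothing ≈ 10% of
height, tile ≈ half the plot's short side) at roughly 1/40 of the pixel
count, which keeps a hundred-scene experiment to tens of seconds. The
tiling identity (15 tiles at offsets {0, 750, 1500, 2250, 2800} ×
{0, 750, 1000}) is checked at the full 3800 × 2000 size, and all defaults
in `pipeline_config()` are the full-scale operating point.

## Known limitations

* One plot per frame, located by a fixed-size window; no orthomosaic
  stitching, geo-referencing or multi-plot layouts.
* CIVE is the only vegetation index; crops or soils where CIVE separates
  poorly would need a different index upstream of the same machinery.
* The merge stage is plain greedy NMS; boxes of the same object split
  across tiles at IoU below the merge threshold would double-count (the
  border-drop rule in the reference detector exists precisely to avoid
  this; trained detectors running on overlapping tiles rely on the overlap
  for the same guarantee).
* Heading dates are argmin over observed dates; sub-day precision or sparse
  flight schedules require interpolation, which is deliberately not
  implemented.
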