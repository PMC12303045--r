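---
title: "Methods: point-annotation cell detection, its codec and its statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: point-annotation cell detection, its codec and its statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdgcellkit)
```

## The problem

Hereditary diffuse gastric cancer (HDGC) lesions are assessed by locating
individual tumor cells — typical signet ring cells, atypical signet ring
cells and non-signet-ring tumor cells — in H&E-stained slides. Automated
detectors for this task are trained from *point* annotations (one dot near
each cell center inside exhaustively annotated lesion polygons) and
evaluated by comparing predicted points against reference points under a
physical hit-radius criterion. `hdgcellkit` implements the model-agnostic
machinery around such a detector: the encoding of points as segmentation
targets, the decoding of segmentation output back into points, the
detection and lesion-level agreement metrics, the reader-study statistics,
and the training-data logistics (weighted patch sampling, hard-negative
mining). Everything runs end-to-end on synthetic slides with known ground
truth; no whole-slide image is required.

## Coordinate and unit conventions

Coordinates are 0-based pixels, origin top-left, `x` = column, `y` = row.
Every set and raster carries its physical pixel size (`spacing_um_per_px`,
default 0.5 µm/px); all physical criteria (the 10 µm hit radius, lesion
buffers, heatmap kernels) are stated in micrometers and converted at the
boundary, so changing the working resolution does not change their meaning.
Human annotations carry *no* confidence, which the toolkit keeps distinct
from confidence 1.0: reader–reader comparisons must never depend on
fabricated confidences.

## The body/membrane codec

Each annotated cell is rendered as an inner disk (the *cell body*, the
segmentation target) surrounded by an annulus (the *cell membrane*), which
acts as a separator so that adjacent cells remain separable in the
segmentation output. The flat label space is: 0 background, 1 healthy
tissue, 2–4 body per class, 5–7 membrane per class.

Per-class geometry defaults to body radius 8/6/5 px and membrane width
3/2/2 px (typical, atypical, non-SRC) at 0.5 µm/px. These are toolkit
defaults that preserve the documented *ordering* of average cell sizes
(typical > atypical > non-SRC); they are configurable and not claimed to be
externally calibrated values.

Rendering order resolves overlaps deterministically: all membranes first,
then all bodies (bodies overwrite membranes); where two bodies overlap,
each pixel goes to the nearest annotation center, with exact ties broken
toward the lower class in the fixed class order. Rasterization of region
polygons uses an even-odd scanline evaluated just above and just below each
pixel row and unioned, which keeps boundary rows inside and matches the
boundary-inclusive point-in-polygon test used everywhere else.

Decoding inverts the codec on (possibly noisy) segmentation output:
membrane labels are treated as healthy tissue, 8-connected components of
each body label are extracted, components with equivalent radius
`sqrt(area/pi)` < 2 px are dropped, and surviving area centroids are
greedily deduplicated at a 10 px minimum distance. We interpret the radius
threshold as *equivalent* radius from area (the standard area-based
reading), apply the centroid suppression *across* classes with a strict
inequality, and keep the larger-area component at each conflict —
conservative readings of rules whose exact definitions are configurable
(`toolkit_config()`). 8-connectivity avoids splitting diagonal pixel
bridges that disk rasters produce. Detection confidence is the mean of the
class-body probability channel over the component's pixels (1.0 when no
probability raster is supplied).

Ensembles of probability rasters are combined by averaging channels and
then taking the per-pixel argmax, ties toward the lower label code. For a
single raster this is an ordinary argmax, so the single-model and ensemble
paths coincide — the deterministic reading of "highest predicted
probability".

## Matching and metrics

A prediction is correct when it lies within 10 µm of a reference
annotation of the same class; matching is one-to-one and greedy:

* **DISTANCE order** (default for reader–reader pairs): admissible pairs by
  ascending distance, ties by prediction then reference index. This is
  symmetric in its arguments, so pairwise F1 matrices are exactly
  symmetric.
* **CONFIDENCE order** (model-versus-reference): predictions by descending
  confidence, each taking its nearest free reference.

Greedy matching is deterministic and standard in detection scoring; it is
a maximal matching, hence never below half the maximum matching, and it
equals the maximum whenever points are separated by more than twice the
hit radius. The exact maximum-cardinality matcher
(`oracle_max_matching()`) ships in the package and the test suite monitors
the greedy matcher against it.

F1 is computed per class and averaged without weights into the overall F1;
a class empty on both sides scores 1, a class empty on exactly one side
scores 0. The any-tumor F1 re-matches class-blind rather than reusing the
class-aware matching. Lesion-level agreement uses two measures:

* count agreement `1 − |a−b| / max(a, b, 1)`. The max-denominator
  normalization is symmetric and bounded in [0, 1] — required for a
  pairwise agreement statistic; the conventional `|a−b|/b` is neither.
* Jensen–Shannon similarity `1 − JSD(a, b)` with base-2 logarithms, so the
  divergence (and the similarity) lives in [0, 1]. Similarity of two empty
  lesions is 1 by convention; empty against non-empty is 0.

## Reader-study statistics

`pairwise_agreement()` scores every unordered source pair per lesion
(default) or per image; `compare_model_to_readers()` pools the model–reader
scores over all readers and lesions and compares them against the pooled
inter-reader scores with a two-sided Wilcoxon rank-sum test. Pooling (not
per-reader averaging) is used because each model–reader pair per lesion is
one observation of the quantity being benchmarked. Confidence intervals
for group means use the t-distribution; test-set style summaries use a
percentile bootstrap (1000 iterations, 2.5/97.5 percentiles) over units —
slides for slide-level F1, lesions for lesion-level metrics.

The Wilcoxon machinery delegates to `stats::wilcox.test` with *fixed*
branch rules so p-values are reproducible across platforms: rank-sum is
exact when `min(n) ≤ 8` with no pooled ties, signed-rank exact when the
effective n (zero differences dropped) is at most 15 with no tied absolute
differences; otherwise the normal approximation with tie/continuity
correction is used. Fully tied inputs yield p = 1 (no evidence of a
shift); all-zero paired differences yield p = 1 with a `degenerate` flag.
The test suite checks both tests against exhaustive enumeration oracles on
all small tie-free inputs.

Agreement heatmaps sum reader point masses on the grid and convolve with a
unit-mass isotropic Gaussian. The kernel standard deviation defaults to
10 µm — the hit radius — so the visualization is consistent with the
scoring criterion; k coincident reader points peak at k times the
single-reader value and total mass approximates the point count.

## Sampling and hard-negative mining

Stage-1 patch sampling uses weights (healthy 0.10, each tumor class 0.30);
stage 2 uses (each tumor class 0.20, each hard-negative class 0.10,
healthy 0.10). "Evenly from the three tumor cell types" is implemented as
even patch counts (not even cell counts within patches). Tumor-class
patches center on a uniformly drawn annotated cell of that class;
hard-negative patches draw samples with probability proportional to their
confidence, so a sample with score x is selected x/y times as often as one
with score y; healthy patches draw uniformly from tissue outside lesions.
"Regions without prior errors" (the stage-2 healthy restriction) is
implemented as additionally excluding a buffer of twice the hit radius
around every mined hard negative — the concept is named without geometry
in the source methodology, and tying it to the hit radius keeps it
consistent and testable. Patch centers clamp so the 512 px window stays in
bounds, rather than inventing a padding policy the codec would have to
honor.

Hard negatives are detections outside every lesion polygon dilated by a
physical buffer; dilation is computed exactly as "inside or within
buffer-distance of the boundary", without constructing offset polygons.
Mining-slide selection takes `ceiling(fraction · n)` slides per
cross-validation fold.

## The synthetic fixture generator

`generate_slide()` emulates the *structure* of an annotated slide: a
tissue polygon, non-overlapping star-convex lesion polygons, and cells
dart-thrown inside lesions with a global minimum spacing and classes drawn
from the dataset-wide mix (0.39, 0.30, 0.31). Defaults: 2048 × 2048 px at
0.5 µm/px, 3 lesions of ~220 px radius, 70 cells each (210 cells per
slide). The default minimum spacing is 23 px =
`2·max(body_radius + membrane_width) + 1`: this guarantees that encoded
bodies of all classes remain pairwise disconnected (disks of radius r can
share 8-adjacent pixels up to center distance `2r + √2`) and therefore
that the encode→decode round trip recovers every cell exactly. Crowded
fixtures with smaller spacing are used separately to exercise the
suppression rules.

`render_probability_raster()` is an oracle segmenter: the ideal one-hot
raster from the codec, optionally degraded by per-pixel label flips,
per-channel Gaussian blur and multiplicative amplitude jitter, then
renormalized. Decoding is extremely robust to independent pixel flips (the
area filter removes speckle, and a body percolates until roughly half its
pixels are gone), so graded degradation in the end-to-end tests is driven
mainly by blur, which erodes the smallest cell class first — a smooth,
seed-stable response. `simulate_reader()` models inter-observer
variability as independent misses, isotropic location jitter, a
row-stochastic class confusion matrix and Poisson spurious points confined
to lesions (readers annotate lesion crops, so false positives outside
lesions are not modeled).

What the simulators deliberately do *not* model: H&E texture and stain
variation, detector failure modes that correlate with morphology, reader
biases that depend on lesion architecture, and annotation drift between
readers. Passing tests therefore demonstrate the correctness of the codec,
metrics and statistics — not the clinical performance of any detector.

## Numerical choices and problem sizes

All generators and samplers are pure functions of their parameters and a
seed (the caller's RNG state is saved and restored). Probability rasters
are stored as rows × cols × 8 arrays; an 8-channel raster at 2048² is
~270 MB, so the end-to-end pipeline examples and tests use 1024² slides
(~60–120 cells), which keeps a full simulated study — slide, three-member
ensemble, five-reader panel, agreement report — in the low tens of
seconds on one CPU. The codec round-trip checks use the full 2048²
default fixtures. Component labelling uses 4-connected labelling from
EBImage followed by a union-find merge of diagonally adjacent label pairs,
which is exactly 8-connected labelling without a per-pixel interpreted
loop.

## A worked example

```{r example, eval = FALSE}
truth <- generate_slide(slide_sim_params(extent_px = c(1024, 1024),
                                         n_lesions = 2,
                                         cells_per_lesion = 60,
                                         lesion_radius_px = 200,
                                         seed = 11))
mask <- encode_points_to_mask(truth)
detections <- decode_mask_to_points(mask)
f1_scores(detections, truth)

readers <- simulate_reader_panel(
  truth, lapply(1:5, function(i)
    reader_noise_params(miss_rate = 0.25, jitter_sigma_px = 8,
                        spurious_rate = 0.1)),
  seeds = 1:5)
model <- truth; model$source_id <- "model"
compare_model_to_readers(readers, model, metric = "F1_OVERALL")
```

## Known limitations

* Greedy matching can fall below the optimal assignment on crowded inputs
  (never below half); the shipped oracle quantifies the gap.
* Polygon operations assume simple polygons; holes and multi-polygons are
  out of scope.
* The reader simulator draws spurious points uniformly within lesions;
  real false positives cluster near ambiguous morphology.
* Pyramidal whole-slide formats and tiled reading are out of scope; inputs
  are point tables, polygons and desk-scale rasters.
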