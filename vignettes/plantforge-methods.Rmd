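---
title: "Methods: exemplar-based plant scene synthesis and leaf posture digitization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exemplar-based plant scene synthesis and leaf posture digitization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantforge)
```

## The problem

Image-based phenotyping of sapling-stage trees under drought stress needs two
things that are expensive to obtain by hand: large annotated training sets for
instance segmentation of plant organs, and a reliable way to turn segmented
organs into interpretable structural traits. `plantforge` addresses both at
desk scale:

1. **Exemplar-based scene synthesis.** A small number of manually annotated
   photographs (leaf blades in green, midveins in yellow, petioles in red,
   trunks in blue) are decomposed into a database of component exemplars.
   New training images are composited by mounting randomly transformed leaf
   exemplars onto a trunk. Because every pasted pixel is tracked, the
   instance annotations of the synthetic scene are pixel-exact by
   construction — annotation comes for free.
2. **Leaf posture digitization.** Given instance segmentations (from any
   segmenter), each leaf is paired with its petiole and midvein by
   intersection-over-union, a straight line $y = kx + b$ is fitted to each
   organ's pixels by least squares, and the horizontal inclination angles
   $\alpha = \arctan(k_{\text{petiole}})$ and
   $\beta = \arctan(k_{\text{midvein}})$ summarize the leaf's posture.
   Drooping (wilting) leaves under drought show systematically lower angles.
3. **Multitask classification scaffold.** A shared image feature feeds two
   classification heads — plant variety and drought-stress level — trained
   against the fused sum of their cross-entropy losses, so stress assessment
   is not confounded by variety differences.

Everything runs on procedurally generated fixtures with known ground truth, so
the full pipeline is testable without photographs.

## Coordinate and angle conventions

Raster images are `[row, col, channel]` arrays in $[0, 1]$; masks are logical
matrices. Pixel coordinates are 0-based with $x$ = column, $y$ = row, origin
top-left; bounding boxes are half-open. Angles are reported in **math
convention** (y up): a leaf pointing above the horizontal has a positive
angle. The image-to-math flip happens in exactly one place
(`mask_pixels_math()`); the fixture renderer performs the inverse flip in its
direction vectors, so the two cancel and ground-truth angles are recovered
directly. Angles live on the axial scale $(-90°, 90°]$, and angle differences
are wrapped modulo 180°, so an 89° vs −89° disagreement counts as 2°, not
178°.

## Annotation parsing and the component database

`parse_annotation_map()` matches palette colors with a per-channel tolerance
(default 30 of 255, surviving JPEG compression and anti-aliasing; tolerance 0
gives exact matching) and labels 8-connected components. Each midvein or
petiole component is assigned to the blade it overlaps most; a component with
no overlap is assigned to the nearest blade within a 5-pixel dilation,
because petioles are often drawn extending just outside the blade. An organ
touching no blade is discarded with a warning. Each exemplar's class masks
are disjoint — every annotated pixel belongs to exactly one mask of one
exemplar — while the *instance* annotations emitted downstream use the union
blade ∪ organs as the leaf region, mirroring source annotations in which the
leaf ROI contains its organs. This union is what makes organ-to-leaf IoU
matching well-posed: a petiole contained in its leaf region has
IoU = |petiole| / |leaf| > 0.

The exemplar's mount point is the petiole pixel farthest from the blade
centroid (the free end of the petiole), falling back to the lowest blade
boundary pixel when no petiole was annotated. Trunk mount sites are taken
every 15 rows along the trunk mask's per-row midpoint curve, restricted to
the upper 80% of trunk height — the source material does not define mount
geometry, so these are package choices that produce botanically plausible
mounts.

## Scene synthesis and occlusion policy

`synthesize_plant()` draws the trunk first (scaled to 90% of canvas height,
bottom-centered), then samples $n \sim \mathrm{Uniform}(5, 20)$ leaves with
replacement, each flipped with probability 0.5, rotated within ±25°, and
scaled within 0.8–1.2 — conservative defaults that keep the structural
pattern of synthetic plants close to real ones. Each leaf is translated so
its attachment point lands on a sampled trunk site and composited in z-order.
Compositing is hard-mask paste with no alpha feathering, precisely so that
annotations stay pixel-exact.

Under the default `visible` (modal) occlusion policy every annotation
contains exactly the pixels where that instance is visible in the composite:
leaf masks are pairwise disjoint and recomputing them from the compositing
z-buffer reproduces them bitwise (this is tested against an independent
sequential painter). The `amodal` policy emits full transformed extents
instead, for ablation. Leaves whose visible fraction falls below 0.25 are
dropped and the scene recomposited (removing a leaf can only increase the
visibility of the others, so one recomposition suffices); organs that end up
fully hidden are dropped while their parent leaf survives. Whether leaves may
occlude the trunk and how many leaves a plant carries are deliberately
config-exposed — the source material fixes neither.

## Mask ↔ polygon conversion

YOLO-style trainers consume one polygon per line; mask-based trainers consume
per-instance rasters. `mask_to_polygon()` traces the boundary of the largest
8-connected component (Moore neighbor tracing with Jacob's stopping
criterion), collapses collinear runs, orients the vertex list
counter-clockwise in image coordinates starting from the
topmost-then-leftmost boundary pixel (a deterministic serialization), and
normalizes vertices at pixel centers by image width and height.
`polygon_to_mask()` draws the polygon edges (so degenerate polygons rasterize
to 1-pixel lines, never empty masks) and fills the interior by even-odd
scanline over pixel centers. For simply connected shapes the round trip is
exact; holes are filled and secondary components dropped by the
largest-component rule, which is what bounds the round-trip IoU at 0.95
rather than 1 for arbitrary masks.

## Line fitting and its bias

Ordinary least squares of $y$ on $x$ is ill-posed for near-vertical organs
(a fully wilted petiole). When the point set spreads more vertically than
horizontally the axes are swapped before fitting and the angle mapped back
via $\mathrm{sign}(k')\,90° - \arctan(k')$; total least squares would remove
the case split but changes the estimator, so it is not the default. Two
numerical facts matter for interpreting recovered angles:

* **Attenuation.** Regressing $y$ on $x$ over a straight stripe of length
  $l$ and width $w$ shrinks the slope by $(l^2 - w^2)/(l^2 + w^2)$; at 45°
  with $l = 22, w = 3$ that is a 1.07° underestimate, falling to 0.59° at
  $l = 30$. The fixture defaults (petiole 30 px, stripes 3 px wide) keep the
  worst case under 1°. This bias is a property of the line-fit method itself,
  not of the fixtures.
* **Minimum evidence.** Organs covering fewer than `min_fit_pixels`
  (default 10, configurable — the threshold is not prescribed by the method)
  are refused; leaves lacking a petiole or midvein are flagged invalid with
  a reason (`NO_PETIOLE`, `NO_MIDVEIN`, `TOO_FEW_PIXELS`) and excluded from
  statistics rather than contributing garbage angles.

Matching is greedy in descending leaf-area order with no organ reuse and
zero-IoU candidates never assigned; ties break toward the smaller candidate
index. On scenes with up to 6 leaves this provably equals the exhaustive
assignment search (tested property). Greedy no-reuse prevents one petiole
serving two leaves, a case the method description leaves open.

## What the fixtures emulate — and what they do not

`render_fixture_plant()` draws elliptical blades carrying straight midvein
stripes, attached by straight petiole stripes, on a near-black background
emulating imaging against a high-absorbance black cloth. The petiole stripe
extends 2 px into the blade and the midvein is inset from the blade tip so
the blade stays 8-connected around it. Ground truth angles are exact by
construction, so the posture pipeline can be scored end to end:
`angle_recovery_experiment()` reports MAE ≈ 0.3–0.4° on 200 clean leaves and
stays below 1° after simulated segmentation degradation (random
erosion/dilation up to radius 2 and up to 20% petiole truncation from the
free end).

Drought populations (`sample_drought_population()`) draw angles from
per-group normal distributions — control ≈ N(25°, 8°), moderate drought ≈
N(5°, 8°), severe drought ≈ N(−35°, 10°), severe-then-normal rewatering ≈
N(30°, 8°), severe-then-moderate rewatering ≈ N(15°, 8°) — encoding only the
qualitative ordering severe < moderate < rewatered ≤ control. The magnitudes
are package choices, not measured values, and group recovery tests assert
the ordering, never the magnitudes.

The classification fixtures encode variety by blade shape (aspect ratio) and
foliage color (green and blue channels varied in opposite directions, so the
green/blue ratio identifies variety independently of blade area) and stress
level by the angle distribution plus a global red tint (browning). The two
factors are generated independently, so permuting one cannot change the
statistics of the other (tested). Real foliage differs in ways these
fixtures do not capture — texture, lighting, self-occlusion among crowded
leaves, continuous variation within a variety — so passing tests demonstrate
that the *pipeline machinery* is correct, not that any accuracy level
transfers to photographs.

## Classification scaffold

The splits are 6:2:2 (train/validation/prediction) stratified by variety
with largest-remainder rounding; by default all rows of one plant stay in
the same partition, since splitting a plant's repeated timepoints across
partitions would leak appearance information (per-image splitting remains
available via `group_by = NULL`). The multitask model puts two independent
one-hidden-layer heads (64 ReLU units) on the shared backbone feature; the
single-task baseline is one linear map. The fused loss is the equally
weighted sum of the two cross-entropies — the weighting is exposed because
the method only specifies "fused", and weights (1, 0)/(0, 1) reduce exactly
to the single-task losses (tested identities).

Training uses minibatch Adam. The full-size default recipe
(`train_config()`: initial learning rate 5e-4 decayed ×0.1 after 20 epochs,
60 epochs, batch 16) follows the standard schedule for fine-tuning
large pretrained backbones. Desk-scale experiments
(`classification_experiment()`) instead use 5e-3 over 30 epochs: the toy
backbone (per-channel mean pooling over a 4×4 grid, 48 features,
standardized with training-set statistics) trains a tiny head in a few
hundred steps, where 5e-4 is calibrated for tens of thousands. The best
checkpoint maximizes validation stress accuracy (the harder task; variety
accuracy is logged alongside), with ties going to the later epoch so that
among equally accurate checkpoints the most-trained parameters are kept.
Training is exactly reproducible under a fixed seed because the
implementation is pure R.

Problem sizes used throughout the test suite and the acceptance script —
50 synthesized scenes at 224×288, 200 fixture leaves per recovery
experiment, 200 leaves per drought group, and 4 varieties × 5 levels × 20
images for classification — were chosen as the smallest sets at which the
measured quantities are stable across seeds.

## Known limitations

* Drooping petioles are curved; a straight-line fit underestimates their
  inclination, and badly truncated segmentations can flip a sign. Curve
  (parabola) fitting is out of scope here.
* The synthesis is 2-D compositing: no lighting model, no perspective, no
  3-D leaf pose. Scenes are "pattern-realistic", not photorealistic.
* The polygon format carries one polygon per instance; instances fragmented
  by occlusion serialize only their largest visible fragment.
* The sign convention (positive = above horizontal) is the package's fixed
  choice; data sources that report wilting as *increasing* angles must be
  negated on import.
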