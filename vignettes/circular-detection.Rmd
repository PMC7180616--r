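---
title: "Circular bounding boxes for round-fruit detection: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circular bounding boxes for round-fruit detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circdet)
```

## Why circular boxes

Detectors for harvesting robots localize fruit that is, to a good
approximation, circular in the image plane. A rectangle around a tomato
carries dead corners: two rectangles on adjacent fruit can overlap heavily
in those corners while the fruit themselves barely touch, and vice versa.
Replacing the rectangle with a circle `(cx, cy, r)` has two consequences
this package is built around:

1. the IoU between two boxes becomes the *exact* circle–circle IoU, which
   tracks actual fruit overlap and therefore gives non-maximum suppression
   and detection matching a cleaner signal; and
2. a box needs three regressed coordinates instead of four, so the
   prediction head shrinks from `B × (5 + C)` to `B × (4 + C)` channels.

`circdet` implements the full machinery around such a detector — geometry,
suppression, anchor priors, prediction decoding and loss, evaluation,
synthetic test scenes, and a structural validator for the densely
connected backbone — while deliberately excluding network training, which
needs field imagery and GPU time and contributes nothing to the
correctness of any of these components.

## Geometry

For radii `R`, `r` at center distance `d` the overlap is a circular lens
whenever `|R − r| ≤ d ≤ R + r`:

$$A = \theta R^2 + \varphi r^2 - \tfrac12 R^2 \sin 2\theta
      - \tfrac12 r^2 \sin 2\varphi,\qquad
  \theta = \arccos\frac{R^2 + d^2 - r^2}{2Rd},\;
  \varphi = \arccos\frac{r^2 + d^2 - R^2}{2rd}$$

with $\mathrm{IoU} = A / (\pi R^2 + \pi r^2 - A)$, reducing to
$(\min(R,r)/\max(R,r))^2$ under containment and 0 when disjoint.

Numerical choices:

* The `arccos` arguments are clamped to `[-1, 1]`. Near internal or
  external tangency floating-point drift pushes them marginally outside
  the mathematical range; clamping makes the lens formula continuous
  across both regime boundaries (verified to `1e-9` in the tests).
* Regime tests use `d >= R + r` for disjoint and `d <= |R - r|` for
  containment; exactly on a boundary the closed forms agree, so the
  tie-break is inconsequential.
* Degenerate circles (`r = 0`) get IoU 0 even against themselves — the
  union area is zero and defining 0/0 as 0 keeps suppression and matching
  total functions.
* Coordinates are continuous 0-based pixels, origin at the image top-left,
  y down; nothing in the geometry snaps to integers.

How circular ground truth is obtained from rectangular annotations is a
convention the field has not settled, so `rect_to_circle()` offers four
radius rules (`mean` of half-sides — the default — `min`, `max`,
`circumscribed`); the default is a middle ground and round-trips exactly
with `circle_to_rect()`.

## Non-maximum suppression

`nms()` is the classic greedy algorithm: select the remaining detection
with maximal confidence, delete every remaining detection with IoU at or
above the threshold `lambda` (the `>=` is deliberate), repeat. Two
decisions needed pinning down:

* **Tie-break.** Equal confidences resolve toward the earlier input row.
  This gives a total order, making the algorithm deterministic and its
  kept set invariant under input permutation — both are tested properties.
* **Threshold default.** `lambda = 0.5`, the community default, exposed
  as an argument everywhere (function, CLI, config) since the right
  operating point depends on how densely fruit cluster.

Suppression is class-agnostic by default (the motivating task has a single
class); `per_class = TRUE` splits by `class_id` first.

## Anchor priors

`kmeans_anchors()` clusters ground-truth dimensions under
`1 − IoU(concentric)` — circles and rectangles compared at a common
center, so the distance reflects size and shape only. Details the
standard anchor recipe leaves open, fixed here as:

* **Initialization**: k-means++-style seeding under the same distance;
  **restarts**: best of `n_restarts` (default 10) by mean best IoU;
  **convergence**: stable assignment or 300 sweeps; **empty clusters**:
  re-seeded from the point farthest from its nearest center.
* **Centroid update**: arithmetic mean of member dimensions, the standard
  anchor recipe (not medoids).
* **Scale split**: the k anchors, sorted by area, are partitioned into
  three groups; the smallest third serves the finest detection scale
  (stride 8), the largest the coarsest (stride 32) — the usual multi-scale
  convention for dividing nine anchors among three detection scales.

`average_best_iou()` (mean over ground truths of the best concentric IoU
to any anchor) is the diagnostic for choosing `k`; it is non-decreasing in
`k` by construction and the tests verify the clustering preserves that
monotonicity with the default restart budget. On synthetic data where
circles are inscribed in aspect-jittered rectangles, circular anchors
score at least as high as rectangular anchors at every `k` — the circle
has one dimension of variation to cover, the rectangle two — which is the
qualitative argument for circular priors, reproduced by the acceptance
suite on the synthetic distribution.

## Prediction head and loss

A detection scale is an `S × S` grid with `B` anchors per cell. Decoding
follows the sigmoid/exponential parameterization:

$$\hat x = \sigma(t_x) + c_x,\quad \hat y = \sigma(t_y) + c_y
  \;(\text{grid units, scaled by the stride}),\quad
  \hat r = p_r e^{t_r}\;(\text{pixels}),$$

with cell offsets `(c_x, c_y)` from the image top-left and prior radius
`p_r`. `encode_box()` is the exact inverse (round-trip identity to `1e-9`
relative, a tested property); centers exactly on a cell edge sit on a
logit singularity and are nudged inward by `1e-6` cell units.

Each ground truth is the responsibility of exactly one (scale, cell,
anchor) slot: the anchor of highest concentric IoU to its radius picks the
scale and anchor, the cell contains its center. Collisions (two ground
truths in one slot) keep the later ground truth and warn — rare at
realistic object densities, but the behaviour must be defined.

The loss sums five terms over all slots: weighted squared error on the
decoded center (grid units) and radius (pixels) over object slots,
cross-entropy confidence terms over object and (down-weighted) no-object
slots, and per-class binary cross-entropy over object slots, with
`lambda_coord = 5` and `lambda_noobj = 0.5` balancing the few responsible
slots against the many empty ones. Design points:

* **Decoded space.** The objective is stated in the decoded
  quantities `x̂, ŷ, r̂`, so the coordinate loss is computed there, not in
  raw t-space. The analytic gradient (`head_gradient()`) threads the
  sigmoid/exponential chain and is checked against central finite
  differences at `1e-4` relative.
* **Confidence target.** `C = 1` for responsible slots. The alternative
  IoU-weighted semantics (`Pr(object) × IoU`) exists in the literature,
  but the no-object term `−(1−C)·log(1−Ĉ)` presumes a binary `C`, so the
  binary form is used.
* **Radius scale.** The radius error is in raw pixels; this overweights
  large fruit relative to a normalized loss, but normalizing silently
  would change the objective, so the pixel form is kept.
* **No ignore region.** Some detector variants exclude near-miss slots
  from the no-object term; the objective implemented here keeps a strict
  object/no-object partition.
* Probabilities are clipped to `[1e-7, 1 − 1e-7]` before logarithms.

## Evaluation

`match_detections()` uses the benchmark convention: detections in
non-increasing confidence order each claim their best-IoU unmatched ground
truth, TP if that IoU reaches the threshold (default 0.5 circular IoU,
exposed as an argument — it is a benchmark convention, not a law),
FP otherwise; unclaimed ground truths are FN. `pr_curve()` sweeps every
*distinct* confidence (tied detections enter together), and
`average_precision()` integrates the all-point interpolated envelope
$p_\text{interp}(r) = \max_{\tilde r \ge r} p(\tilde r)$ — the literal
maximum, not the 11-point approximation. `prf_at_threshold()` reports the
single-threshold recall/precision/F1 triple (the conventional reporting
point is confidence 0.8, the default).

For detector comparison, `subsample_ap()` draws `n_subsets` random image
subsets (default 30 subsets of 80 images — sampling without replacement
within a subset, independently across subsets, the simplest defensible
overlap policy) and `wilcoxon_signed_rank()`
runs the paired two-sided test: zero differences dropped, mid-ranks for
ties, exact enumeration of all `2^n` sign assignments up to 12 effective
pairs, continuity-corrected normal approximation with tie-corrected
variance beyond. Decisions are read at the conventional `alpha = 0.05`.

## Synthetic scenes: what they emulate, and what they do not

`generate_scene()` stands in for field imagery. It renders filled
quasi-circular objects with radial shading over a cluttered background,
places a controlled fraction of objects overlapping a neighbour, draws
elliptical leaf-like occluders over a subset, and labels every object with
its *measured* occlusion fraction (from the rendered ownership masks, so
tags are exact, not approximate) and the scene's illumination regime.
Ground truth is amodal: the circle covers the full fruit extent even where
hidden, matching how partially hidden fruit is annotated in practice.

Defaults, chosen once as representative of orchard/greenhouse imagery at
the standard 416 px detector input: 3–8 objects per scene; log-normal
radii (`meanlog = log(28)`, `sdlog = 0.35`, i.e. mostly 15–55 px); 30%
of placements overlap an existing fruit at center distances of 0.65–0.95
of the radius sum (real fruit clusters touch and occlude, but two fruit
rarely coincide); half the objects occluded with target coverage 0.6 —
deliberately past the 50% boundary that separates "severe" from "slight"
occlusion, so both strata are populated; sunlight (bright, higher
contrast) and shading (dark, flat) regimes drawn with equal probability.

`perturb_detections()` closes the loop without a trained network: misses,
center/log-radius jitter, Poisson false positives, and a confidence model
in which a true detection's confidence decreases with its realized jitter
while spurious detections draw low-skewed confidences — enough structure
to produce non-degenerate precision–recall curves with planted, exactly
known operating characteristics.

`augment_scene()` reproduces the training-time augmentation: with equal
probability the identity or scale-by-`U[1.15, 1.25]`-then-random-crop
back to the original size, followed by a horizontal flip with probability
0.5. The two augmentation options are weighted equally; nothing in the
pipeline's rationale favours one over the other. Ground-truth circles
whose centers leave the crop are dropped; centers inside keep their circle
even if partly cut.

**Limits.** Passing tests on these scenes demonstrates that the geometry,
suppression, assignment, loss and evaluation machinery is correct and that
the evaluation pipeline recovers planted error rates. It does not
demonstrate detection performance on real imagery: the generator has no
color, no perspective, no texture families, no correlated lighting, and
its "detector" is a noise model, not a network. No synthetic number
should be compared against accuracy figures obtained on real field
datasets.

## Architecture validation

`build_graph()` constructs the backbone declaratively: five dense blocks
of 6/12/24/16/16 layers (each layer a 1×1 bottleneck plus a 3×3
convolution over the concatenation of everything before it, giving
`L(L+1)/2` direct connections per block), transition layers between
blocks, and three detection branches of exactly two convolutions each —
pruned from the conventional six on the strength of dense feature reuse —
emitting `B × (4 + C)` channels for circular boxes. Unpinned widths
follow DenseNet conventions, configurable: growth rate 32, bottleneck
width 4× growth, transition compression ½ with stride-2 downsampling.
Transitions sit between consecutive *blocks*, not between individual
dense layers — the only placement consistent with five blocks feeding a
stride-32 coarse scale — and the inter-scale
routing (1×1 route convolution, upsample, concatenate) follows the
standard multi-scale pattern — route convolutions are bookkept outside the
two-convolution detection branches. `validate_graph()` checks all of this
structurally; `count_params()` does the weight arithmetic
(`k²·in·out + 2·out` batch-norm terms per convolution, bias instead of
batch norm on prediction layers). No tensors are ever allocated; training
schedules are out of scope, and the defaults for them (416×416 input,
batch 8, 160 epochs, learning rate 1e-3 divided by 10 at epochs 60 and 90,
momentum 0.9, weight decay 5e-4) are recorded in the CLI config as
documentation only.

## Problem sizes in the test suite

The suite verifies geometry against a Monte-Carlo area oracle (500 random
pairs across all three regimes, 10⁶ samples each, bounded at 6 standard
errors per pair with the count beyond 3 SE held to its Poisson 99.9%
tail), suppression against a brute-force reference (1000 random instances,
up to 50 detections), encode/decode round trips (1000), AP against
exhaustive threshold enumeration (300 small instances), and the full
synthetic loop at 200 scenes with planted 7% miss / 5% false-positive
rates. These sizes make the statistical assertions sharp while keeping a
full run around a minute on one core; all seeds are fixed.

## Known limitations

* Geometry is exact for circles and axis-aligned rectangles only; no
  ellipses, rotated boxes or polygon IoU.
* The loss module evaluates and differentiates the objective but does not
  train; there is no tensor backend.
* Wilcoxon p-values below `2^-n` are unreachable by the exact method, and
  the normal approximation is a large-sample device — with 30 subsets it
  is accurate, with fewer than ~15 prefer the exact path.
* The synthetic renderer is grayscale and single-class.
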