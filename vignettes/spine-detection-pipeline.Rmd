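---
title: "Detecting and tracking dendritic spines in 3D image stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and tracking dendritic spines in 3D image stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(spinetrack)
```

## The problem

Dendritic spines are micrometre-scale protrusions of a neuron's dendrite
and a morphological proxy for excitatory synapses. Two-photon microscopy
images them in vivo as z-stacks: ordered grayscale optical slices (here
512 × 512 px at 0.1 µm/px, 0.5 µm between slices, 8-bit after intensity
clipping at 255). A detector proposes an axis-aligned bounding box with a
confidence for each spine candidate on each slice; the scientific object
of interest, however, is the *spine in 3D* — one identity spanning a
contiguous range of slices. `spinetrack` provides everything around the
per-slice detector: detection post-processing, z-axis tracking into 3D
spine tracks, overlap metrics and F1-style evaluation in 2D and 3D,
fusion of several annotators' labels into consensus ground truths, and a
synthetic stack generator so that the whole chain can be validated
end-to-end with exactly known ground truth.

The per-slice detector itself is pluggable. Production users will
typically wrap a trained region-proposal CNN behind
`register_detector()`; the package ships a deterministic classical
detector (`reference_detect()`: smoothing, background subtraction,
thresholding, connected components, shape filtering) so that the full
pipeline runs and can be tested without any trained network.

## Overlap metrics: IoM instead of IoU

Spines are small relative to the field of view. With the conventional
Intersection over Union, a detection that covers a spine entirely but is
slightly larger or offset is punished hard, which misrepresents the
annotation quality. The package therefore scores in-plane overlap by the
*Intersection over Minimum*,

$$IoM_{xy}(D, G) = \frac{|D \cap G|}{\min(|D|, |G|)} \in [0, 1],$$

which is 1 whenever one box contains the other and always at least the
IoU. Because an absurdly large detection box would also score 1 against
any ground truth it covers, boxes with an area above 2000 px² (20 µm²)
are discarded beforehand: observed spine areas are roughly 100–700 px²
and never exceeded 1300 px².

Depth overlap of two slice intervals is scored analogously
(`iom_z()`). The printed interval-length form $z_2 - z_1$ is zero for a
single-slice spine, so the package defaults to counting slices
($z_2 - z_1 + 1$, the `"slice_count"` convention) and keeps the raw
difference available as `"literal"` with the degenerate cases defined
explicitly. For the same reason the mean box of a track averages over
the number of covered slices rather than the raw interval length.

The two components combine through the weighted harmonic mean
$F_{0.5}$:

$$IoM(D, G) = \frac{5 \, IoM_{xy} \, IoM_z}{IoM_{xy} + 4 \, IoM_z},$$

which emphasises in-plane agreement over depth agreement. A detection
counts as a 3D true positive when some ground truth reaches
$IoM \ge 0.5$; ground truths reached by no detection are false
negatives; the $F_1^{3D}$ score is $2TP/(2TP + FP + FN)$.

Two matching conventions are provided because the TP/FP/FN definitions
above are *existential*: two detections of the same spine both count as
true positives. That is the default (`matching_mode = "existential"`);
`"one_to_one"` performs greedy unique pairing by descending IoM for
users who prefer the stricter bipartite semantics. Ties in the greedy
assignment break by lower detection index, then lower ground-truth
index, so results are deterministic. An all-empty comparison
(`tp = fp = fn = 0`) is reported as `f1 = 0` with a warning rather than
NaN.

## Post-processing and tracking

Raw per-slice detections are reduced to "relevant" detections by three
subset-only filters, in this order: confidence strictly above 0.5, box
area at most 2000 px², then greedy duplicate suppression that keeps only
the most confident of any group of same-slice boxes with pairwise IoM
strictly above 0.5. All three inequalities are strict, matching the
rules' wording ("greater than", "exceeding", "more than"); the boundary
behaviour is pinned down by tests. Cheap per-box filters run first so
duplicates are resolved only among plausible boxes.

Tracking iterates over slices from the top of the stack. Active tracks
are matched to the current slice's detections greedily by descending
in-plane IoM between the track's last observed box and the detection,
accepting pairs only while the score strictly exceeds 0.5 and using each
side at most once. Unmatched detections open new tracks; unmatched
tracks count a miss and are terminated after two *consecutive* misses,
so a spine absent from a single slice survives. During a gap a track is
represented by its last observed box — the simplest stateful choice
consistent with the two-miss rule. After the final slice, each track's
z-interval spans its first to last actual detection; interior gap slices
receive boxes interpolated linearly between the flanking detections
(`interpolate_gaps = FALSE` carries the last box instead); the track's
confidence is the maximum over its member detections (a track is as
credible as its best detection); single-slice tracks are kept, since no
rule says to drop them. New ids are assigned in order of first
appearance, left to right, making the output reproducible.

## Consensus ground truth from several annotators

Rectangular labels from $k$ annotators (VIA-project JSON or flat CSV)
are first turned into 3D tracks with exactly the same tracking rule as
model detections, so humans and models live in one representation. All
annotators' tracks are then clustered by single linkage on the graph
joining tracks of *different* annotators with combined IoM ≥ 0.5. The
clustering rule is an artifact decision — any rule that counts
annotators per putative spine would do — and the simplest one is used.
If two tracks of one annotator fall into a cluster, the one agreeing
better with the other members stays and the other becomes its own
cluster, so each annotator supports a spine at most once and every
track lands in exactly one cluster.

Each cluster's representative track takes the rounded mean of the
member z-endpoints as its interval and, on each slice, the
coordinate-wise mean of the member boxes (members not covering a slice
contribute their nearest covered box). Fusing at support level $k$
keeps clusters backed by at least $k$ annotators: with five annotators,
$k = 1, 3, 5$ give the minimal, majority and maximal ground truth, and
by construction these nest. Whether the original fusion operated on 2D
boxes per slice or on 3D tracks is not documented anywhere; this
package fuses 3D tracks, and per-slice 2D fusion is available simply by
treating each slice as a depth-1 stack.

## Detector-side geometry

For users training a region-proposal detector, the package provides the
anchor-grid geometry (`generate_anchors()`: scales {8}, strides
{4, 8, 16, 32, 64} px, aspect ratios {0.5, 1, 2}, base side =
scale × stride, centres on the half-stride grid, unclipped — the
convention of the Faster R-CNN family), the label-assignment rule for
anchors (per ground truth, the argmax-IoU anchor is positive iff that
IoU ≥ 0.7; anchors below IoU 0.3 against every ground truth are
negative; the rest are ignored — a stricter rule than the standard one,
which is available via `rule = "standard"`), the eight-orientation
augmentation group with box-consistent transforms plus optional
Gaussian noise and blur (each applied with probability 0.5; the noise
and blur magnitudes are not pinned down by any source, so they default
to 5 gray levels and 1 px and are exposed as arguments), and the
combined two-stage loss arithmetic with regression weight α = 2 and L2
weight λ = 3 × 10⁻⁶. The component losses themselves, and all training,
are deliberately out of scope — they belong to the deep-learning
framework hosting the CNN.

On the default 512² configuration the closed form gives
3 × (128² + 64² + 32² + 16² + 8²) = 65,472 anchors. A frequently quoted
count of 50,700 for these parameter lists is not reproducible from any
assignment of the stated scales, strides and ratios; the package
documents the closed form and its enumeration agrees with it exactly,
so 65,472 is what `anchor_count()` reports.

## The synthetic generator

`simulate_stack()` renders stacks whose statistics emulate the target
data, with exact ground truth:

* geometry first (`simulate_ground_truth()`): stack depth drawn from a
  truncated normal (mean 19.5, SD 11.5, clamped to 5–68 slices — the
  published depth statistics of the reference dataset), two dendrites
  as smooth random spline curves, 15 spines per stack (≈ the observed
  ~860 spines over 55 stacks);
* each spine is an ellipse with a target *bounding-box* area uniform in
  100–700 px² (hard cap 1300 px²), random axis ratio in [1, 2],
  oriented along its attachment direction, placed offset from the
  shaft so that its box clears the dendrite's bright halo by ≥ 2 px
  (`attached = TRUE` reproduces the hard overlapping regime);
  placements are rejection-sampled to be mutually non-overlapping and
  inside the image, and an infeasible request errors rather than
  silently overlapping;
* a contiguous z-extent of 2–7 slices with in-plane size and intensity
  peaking at the central slice (an ellipsoid-like profile floored at
  0.35 so end slices remain visible);
* rendering: dendrites as tubes with Gaussian cross-section whose core
  saturates after clipping at 255, spines as Gaussian-profile ellipses
  (peak amplitude uniform in 140–300, so a fraction saturates),
  max-composited, plus Gaussian background noise (SD 8 over an offset
  of 12) and 8-bit clipping.

The per-slice ground-truth boxes are the analytic tight bounds of the
spine's elliptical support, in continuous coordinates. The generator is
bit-deterministic under its seed.

`perturb_annotations()` models annotator variability on top of a known
ground truth: whole-spine misses (drop probability), per-slice Gaussian
corner jitter, z-endpoint jitter, and Poisson spurious boxes.
`make_annotator_panel()` produces independent simulated annotators over
one ground truth.

What the simulator does *not* model: optics-accurate point-spread
functions, photobleaching, motion artifacts, axons and other confusing
bright structures, and (by default) spines overlapping the dendrite in
the image plane. Passing tests on synthetic stacks therefore validate
the *pipeline machinery* — metrics, filtering, tracking, consensus —
not the hard vision problem a trained CNN solves on real tissue.

## Numerical conventions

Boxes live in continuous pixel coordinates, origin at the image's
top-left, x rightward, y downward, with area
$(x_{max}-x_{min})(y_{max}-y_{min})$ and no ±1 pixel adjustments
anywhere; slice indices are 0-based. VIA rectangles import as
$(x, y, w, h) \mapsto (x, y, x+w, y+h)$ exactly, with the slice index
taken from the trailing integer of the image filename stem (no
serialization of slices into filenames is standardised anywhere, so one
deterministic rule is fixed and documented). Detection CSVs round-trip
losslessly to six decimals. All randomness flows from explicit seeds.

## Validation at scale

The test suite closes the loop end to end, at the generator's full
default problem sizes:

* closed-form IoU/IoM agree with a 0.01-px rasterisation counting
  oracle on 1000 random box pairs;
* the F₀.₅ combination is verified against its direct evaluation on
  1000 random track pairs, saturating at 1 exactly when both components
  are 1;
* feeding 20 simulated stacks' unperturbed ground-truth boxes through
  post-processing and tracking reproduces every ground truth exactly
  (F₁³ᴰ = 1);
* the one-miss-bridged / two-miss-split behaviour is pinned by hand
  fixtures;
* across 50 simulated 5-annotator panels the fused ground truths nest
  (maximal ⊆ majority ⊆ minimal), and zero-noise panels give every
  annotator F₁³ᴰ = 1 against all three;
* mean F₁³ᴰ over 10 simulations degrades monotonically as annotation
  corner jitter grows through {0, 1, 2, 4, 8} px (the jitter levels
  share underlying random draws, so the degradation is a coupled,
  noise-free comparison);
* anchor enumeration matches the closed-form count on 100 random
  configurations.

`scripts/acceptance.R` recomputes all of these quantities from scratch
against the installed package and writes them to JSON.

## Known limitations

The existential matching mode can reward over-segmentation (two
detections of one spine count twice); use `one_to_one` when that
matters. The classical reference detector is a transparent test vehicle
tuned on the simulator, not a competitive spine detector for real
tissue. Consensus fusion assumes annotators label the same stack in the
same coordinate frame; no registration is performed. Time-series
identity of spines across imaging sessions is out of scope.
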