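---
title: "Flow-field cell segmentation, style-routed ensembles and
  human-in-the-loop retraining: models and design choices"
author: "flowseg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flowseg methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The segmentation model

`flowseg` segments cell instances in 2D microscopy images with the
flow-field representation: every pixel inside a cell carries a unit vector
pointing toward the cell's centre, plus an inside-cell probability. A label
map is converted to this representation by `masksToFlows()`: for each ROI a
scalar heat field is diffused from the ROI's centre (the per-axis median
coordinate snapped to the nearest in-ROI pixel, which stays inside concave
shapes such as crescents), and the flows are the unit-normalized spatial
gradient of that field. Diffusion runs `2 * longest-bbox-axis` iterations of
nine-point neighbourhood averaging with a unit heat source at the centre;
gradients whose magnitude is below `1e-9` of the ROI maximum (the symmetric
centre pixel) are left at zero rather than blown up by normalization.

`followFlows()` inverts the construction: every pixel whose inside
probability exceeds 0.5 is advected along the flow field with fixed-step
Euler integration (200 steps of 1 px, bilinear flow interpolation, positions
clamped to the canvas). Pixels whose trajectories end within 2.5 px of each
other share a sink and form one ROI; reconstruction of an occupancy mask of
rounded sink positions, dilated by the merge radius and connected-component
labelled, implements the merge. ROI smaller than 15 px are dropped — the
minimum size is a configuration knob (`qcConfig()`), chosen as common
practice for objects of ~10 px diameter.

The round trip `masksToFlows() -> followFlows()` is the contract: on random
convex-cell scenes the reconstruction recovers the original masks at mean
per-ROI IoU well above 0.9 (in practice essentially 1.0); the acceptance
suite asserts the 0.9 bound over 50 seeded scenes.

**Flow-error quality control.** For each reconstructed ROI,
`flowError()` compares the predicted flows inside the ROI with the flows
recomputed from the reconstructed ROI itself; the score is the mean squared
difference averaged over pixels and the two vector components. On this
scale self-consistent flows score ≈ 0 and unrelated flows ≈ 1 (each
component of two independent unit vectors has variance 1/2), so the
rejection threshold 0.4 sits cleanly between the regimes. The threshold is
honored on the package's own scale because the reference implementation's
internal flow scaling is not part of the published description.

# The network

`buildNetwork()` constructs a U-net with residual blocks: each block is
conv3x3 → batch-norm → ReLU → conv3x3 → batch-norm plus an identity (or
1x1-projected) skip, encoder levels double channels and halve resolution
via 2x2 max pooling, and the decoder mirrors them with nearest-neighbour
upsampling and skip concatenation. Three 1x1-conv outputs give the
inside-cell logit and the two flow components. The default configuration
(4 levels, 32 base channels) carries a 256-dimensional style vector; desk
tests use 2 levels with 8-16 base channels.

The **style vector** is the global average pool of the deepest feature
maps, L2-normalized. When `broadcastStyle = TRUE` the normalized style
vector is linearly projected per decoder level and added as a per-channel
bias after the first normalization of each decoder block — the simplest
wiring that makes the broadcast ablation meaningful; the exact original
wiring is not published. With `broadcastStyle = FALSE` the vector is still
computed (so routing works) but never injected.

Two numerical choices matter:

* **Batch-norm uses tracked running statistics at inference** (momentum
  0.1). Per-image statistics would erase exactly the global intensity and
  texture statistics that style vectors must carry; with running statistics
  the style embedding separates image classes reliably.
* **Input normalization** rescales each channel to its 1st-99th percentile
  range, the common practice for this model family; images are padded
  (edge-replicated) to a multiple of the network stride.

The forward and backward passes are implemented directly (im2col/col2im and
pooling kernels in C++, matrix products through BLAS) and verified against
numeric differentiation in the test suite.

# Training

`trainModel()` runs SGD with momentum 0.9 on the combined loss: binary
cross-entropy on the inside map plus mean-squared error on the flows, with
the unit flow targets scaled by `flowAmplitude = 5` following the cited
flow-field training construction; both weights are exposed in
`trainConfig()`. The three schedules are:

| mode | epochs | weight decay | peak lr | anneal |
|---|---|---|---|---|
| offline | 300 | 1e-4 | 0.1 | halve every 5 epochs after 250 |
| online | 100 | 1e-4 | 0.1 | none |
| generalist | 500 | 1e-5 | 0.2 | halve every 10 epochs after 400 |

All warm up linearly over the first ten epochs. Epochs sample the image
list with replacement into batches of eight, with a minimum of eight images
per epoch (smaller sets are resampled); images with fewer than five ROI are
excluded. Augmentation applies one geometric transform to image, inside map
and flows together — rotation uniform in [0, 360°), scale jitter
[0.75, 1.25], flips, ±10% intensity jitter, crop to the training tile —
with flow *vectors* rotated and reflected with the frame so they still
point at the transformed centres.

# Synthetic scenes and annotation styles

`generateScene()` renders non-overlapping cells (disks, ellipses or blobby
polygons) with flat, granular (image-wide multiplicative speckle) or
membrane-bright texture, optional nucleus channel, additive Gaussian noise,
and optional *orphan nuclei*: nuclei whose cell has no cytoplasmic signal,
rendered only in the nucleus channel but present in the biological-truth
label map. Placement is rejection sampling under a hard no-overlap
constraint and a packing-fraction cap (targets above 0.9 are rejected).

`applyStyle()` turns biological truth into one annotator's ground truth:
orphan nuclei kept or dropped, outlines dilated/eroded by up to 3 px
(dilation is simultaneous and stops at collisions, so ROI never merge),
dense neighbourhoods or dim ROI skipped. `makeTwoStyleBenchmark()` builds
the two-class conflict used throughout: class A (flat texture) labels
orphan nuclei, class B (granular texture) does not.

What the generator does *not* emulate: optics (no point-spread function),
overlapping cells in the truth map (overlap handling is exercised
separately through `removeOverlaps()`), uneven illumination, and real
annotator variability beyond the parametric styles. Passing tests therefore
demonstrate the machinery — targets, reconstruction, routing, the training
loop and the relative orderings between strategies — not absolute
performance on real microscopy.

# Desk-scale experiment design

All benchmark experiments run on one CPU in minutes; their problem sizes
are package design choices, stated here once:

* scenes are 48 x 48 px with ~8-12 cells of ~9 px diameter;
* networks have 2 levels and 8 base channels (16-dimensional styles);
* the *source* domain (pretraining, 6 scenes, 80 epochs) is clean flat
  disks; the *target* domain is noisy, crowded, variably sized
  membrane-textured blobs — different enough that a pretrained model
  misses over half the target cells before adaptation;
* `fineTuneExperiment()` gives fine-tuned and scratch models the same
  20-epoch budget on the same 1 target image and measures test AP@0.5 over
  5 replicate seeds;
* `hitlExperiment()` runs 5 annotation rounds (the published workflow
  annotates five training images sequentially) with 45-epoch online
  retraining per round against a 45-epoch offline baseline, 5 seeds. Both
  schedules are long enough to reach their plateau at this problem size;
  at paper scale the published 100/300-epoch budgets play the same role.
  Both arms share a desk-scale peak learning rate of 0.05 — half the
  published 0.1, matched to networks with roughly 1/100th the parameter
  count, where gradient noise at the published rate dominates the final
  constant-rate snapshot of the never-annealed online schedule. The
  experiment's simulated annotator accepts predictions only at IoU ≥
  0.75: "correctly segmented" is a stricter notion than the 0.5 reporting
  threshold, and accepting sloppy masks as training labels destabilizes
  the short online retraining (the `hitlConfig()` default remains 0.5).
* `ensembleExperiment()` trains a generalist on the two-style benchmark
  (5 labeled images per class), clusters style vectors of a larger corpus
  (the 10 labeled plus 20 style-only scenes) with Leiden, fine-tunes one
  specialist per cluster from the generalist's weights (20 epochs) — the
  desk-scale analog of giving every specialist a full training run, since
  scratch-trained specialists at these budgets are undertrained relative
  to a generalist that sees twice the data — and routes test images by
  5-NN on member styles. Clusters without usable training images fall
  back to the generalist checkpoint.

# Style clustering and routing

`clusterStyles()` follows the published protocol — a K-NN graph on
Euclidean distances, partitioned by the Leiden algorithm at resolution
0.45 with 100 neighbours (capped at n-1) — with one addition required at
desk scale: on small sets the capped K-NN graph is complete, and an
unweighted modularity partition of a complete graph can never split. Edges
therefore carry locally scaled Gaussian weights
(`exp(-d^2 / (sigma_i * sigma_j))`, `sigma_i` the distance to the
`ceiling(k/3)`-th neighbour), a standard local-scaling construction that
leaves large-set behaviour unchanged and recovers planted clusters exactly
on separated blobs. Cluster ids are relabelled contiguously from 0 in
first-appearance order, and the partition is deterministic under the seed.

Routing (`assignCluster()`) is a majority vote among the five nearest
clustering members, ties broken to the lowest cluster id. Style vectors are
L2-normalized before clustering and routing; the published description does
not state this either way, and normalization stabilizes K-NN distances.

# The human-in-the-loop driver

`simulateCorrection()` is an idealized, perfectly consistent annotator:
predictions matched one-to-one to truth at IoU ≥ 0.5 are accepted verbatim,
every other truth ROI is copied in as manual work (the copied stroke wins
pixel conflicts), and unmatched predictions are deleted as incorrectly
segmented. `runHitl()` segments image r with the current model, corrects,
then retrains on all corrected images so far with the online schedule,
re-initialized each round from the original starting checkpoint (matching
the published retraining protocol; `warmStart = TRUE` chains rounds
instead). The accounting identity `accepted + manual = ROI of the corrected
map` holds exactly per round.

# Evaluation

`averagePrecision()` implements the dataset-matching AP,
`TP / (TP + FP + FN)`, after one-to-one matching at each IoU threshold,
averaged unweighted over images. Matching maximizes total matched IoU by
optimal assignment (a Hungarian solver; a greedy mode exists and agrees
whenever best matches are uncontested). Edge cases: empty truth and empty
prediction scores 1; empty truth with predictions scores 0. The exhaustive
enumeration oracle in the test suite confirms exact agreement on hundreds
of small instances. `withinAnnotatorBound()` compares two annotation passes
of the same images, the second performed on mirrored copies and mirrored
back, giving the within-annotator upper bound on model performance.

# Known limitations

* The networks are CPU-sized; nothing here aims at full-scale weights or
  weight compatibility with released checkpoints.
* The simulated annotator is perfectly consistent; human style drift and
  deletion errors are not modelled.
* Fractional training-set sizes below a quarter image are not supported.
* 16-bit label maps round-trip through TIFF; PNG output is 8-bit.
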