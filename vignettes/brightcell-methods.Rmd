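---
title: "Detecting cells in brightfield z-stacks: model, training and domain adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cells in brightfield z-stacks: model, training and domain adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Counting cells in label-free brightfield microscopy is hard because cell
contrast is weak and appearance varies drastically between cell lines: some
lines grow as separated, high-contrast cells, others as dense low-contrast
sheets with no visible background between neighbours. A focus stack
(z-stack) helps: a cell's appearance inverts as the focal plane crosses the
cell — darker than background on one side of focus, brighter on the other —
while non-cell debris (e.g. dust on optics) barely changes. A detector that
sees several focal planes at once can exploit this signature.

`brightcell` implements a complete detection pipeline around this idea:

1. a **reduced U-Net** that maps three consecutive focal planes to a
   full-resolution cell-confidence heatmap,
2. **supervised training** from point annotations rasterized as small disks,
3. **iterative unsupervised domain adaptation** that transfers a detector
   trained on one annotated cell line to an unseen line without a single
   new annotation,
4. **evaluation machinery**: distance-based matching with precision /
   recall / F1, and density-stratified accuracy profiles,
5. a **synthetic z-stack simulator** so that every stage can be exercised,
   tested and benchmarked without microscopy data.

## Detector architecture

The detector is a fully convolutional encoder–decoder
(`model_config()`, `build_detector()`). Each of `depth = 3` encoder levels
applies two 3×3 same-padding convolutions with ReLU and then 2×2
max-pooling; channel counts start at `base_filters` and double per level. A
two-convolution bottleneck sits below, and the decoder mirrors the encoder
with 2×2 nearest-neighbour upsampling and channel-concatenating skip
connections. A 1×1 convolution with a sigmoid produces the heatmap, so
outputs live in [0, 1] at input resolution.

Depth 3 is one level fewer than the canonical four-level U-Net. The
rationale: intermediate layers of the full network already carry clean
detections for this task, so one level can be removed — keeping the
symmetric shape — at a large saving in parameters and computation. The
`n_parameters()` helper makes the capacity ordering explicit; the exact
filter inventory at each level is configurable (`base_filters = 16` by
default, 8 in the desk-scale experiments).

Because the network is fully convolutional, any input whose height and
width are divisible by `2^depth` is valid; training exploits this by
switching patch sizes between training cycles. Same-padding keeps the
output at input resolution; the border of each patch carries reduced
context, which is one reason fresh patches are cropped every cycle.

The forward/backward pass, binary cross-entropy loss, and SGD with
Nesterov momentum are implemented in compiled code (`src/unet.cpp`) using
im2col convolution lowering onto BLAS matrix products, in single
precision. Analytic gradients are verified against finite differences in
the test suite. Weights are initialized Glorot-uniform with zero biases:
with the aggressive 0.1 initial learning rate used here, ReLU-targeted
(He) initialization regularly diverges in the first epochs, while
Glorot-uniform — the default of the frameworks this training recipe
originated in — trains stably.

## Training targets and class balance

Point annotations become binary masks (`make_target_mask()`): a disk of
radius 8 px around every cell centre. A disk is the set of pixels whose
squared distance from the centre is at most the squared radius — the usual
morphological structuring element, 197 px at radius 8. When two cells'
disks would touch (share or 8-neighbour a pixel), both radii shrink to
`floor((d − 1)/2)` at centre distance `d` (minimum over all conflicting
neighbours, floored at 1 px), with a final safeguard pass that resolves
residual diagonal adjacency. Touching markers would otherwise merge into
one blob and cost the peak extractor a detection. Whether one or both
radii of a touching pair should shrink is a genuinely open choice; the
symmetric rule was chosen because it is deterministic and
order-independent.

At the reference geometry (twelve 1196×1596 images, 5878 cells, radius-8
disks) the background:cell pixel ratio is ≈ 19:1 — an imbalance mild
enough that plain unweighted pixel-mean binary cross-entropy suffices;
imbalance is managed through the marker radius rather than loss weights.

`rescale_pair()`/`rescale_dataset()` implement the size augmentation used
to prepare for smaller-celled target lines: images and annotations scaled
to 75 %, mask radius proportionally reduced to 6 px, appended to the
original set (doubling it).

## Supervised schedule

`train_schedule()` fixes the recipe: SGD with Nesterov momentum 0.8,
batch size 5, learning rate 0.1 halved after every 10-epoch cycle, 60
epochs total, one quarter of the images held out for validation, and the
patch size switched at every cycle boundary while fresh random patches
are cropped (crop-offset jitter doubles as translation augmentation).
Augmentation (`augmentation_params()`) uses right-angle rotations and
flips — exact pixel permutations, so masks stay binary without any
interpolation policy — plus image-only photometric transforms whose
magnitudes scale with each patch's dynamic range (intensity shift ±10 %,
Gaussian noise σ = 2 % of range; fixed absolute magnitudes would be
meaningless on standardized inputs). Weights are kept from the epoch
with the lowest validation loss (`checkpointed` column of the history).

Patch sizes are not prescribed by the recipe beyond divisibility by
`2^depth`; the package default cycle `c(64, 96, 48, 80, 64, 96)` suits the
128×128 desk-scale geometry, and `c(256, 384, 192, 320, 256, 384)` is the
corresponding full-frame choice.

## Iterative unsupervised domain adaptation

`adapt_iteratively()` transfers a source-trained detector to a new cell
line using only unlabeled target images. Each of 6 cycles:

1. predict heatmaps for 4 images sampled from the unlabeled target pool
   (held-out test images are never in the pool);
2. extract local peaks at threshold 0.2 with minimum distance 5 px — the
   threshold is deliberately low so weak, uncertain detections also
   become training signal;
3. dilate each peak into a radius-6 disk to form pseudo target masks
   (plain disk union, unlike manual masks these are not shrunk);
4. train 10 epochs on a pool of 50 % annotated source patches and 50 %
   pseudo-labeled target patches, halving the learning rate and switching
   patch size per cycle as in supervised training.

The annotated source half is the safeguard: pseudo-labels inevitably
contain false positives and negatives, and training on them alone lets
those errors amplify across iterations. Keeping half the gradient signal
anchored to manual annotations prevents that. The package never reads
target-domain annotations during adaptation — they exist in the synthetic
bundles only for scoring.

Open choices resolved here (the recipe leaves them unstated): the
learning-rate ladder restarts at 0.1 and halves per cycle, mirroring the
supervised phase; the 4 target images are re-sampled every cycle (labels
are regenerated each cycle anyway); validation during adaptation uses a
held-out quarter of *annotated source* patches, and each cycle's
best-validating weights — the cycle's starting weights if nothing
improved — carry into the next cycle. Source-only validation is
deliberate: pseudo-labels cannot serve as validation ground truth,
because a detector that collapses to predicting background everywhere
scores deceptively well against its own near-empty pseudo-masks. With
manual annotations as the yardstick, such a cycle validates badly and is
rolled back instead of feeding even emptier pseudo-labels to the next
iteration.

## Detection and evaluation

`detect_cells()` is the strict composition triplet → heatmap → peaks; the
inference peak parameters default to the auto-labeling values (0.2 / 5 px)
since nothing in the recipe distinguishes them.

`match_detections()` scores a detection set against ground truth: a pair
may match when their Euclidean distance is strictly below 20 px, and when
several candidates lie within the radius only the closest is accepted.
This is realized as greedy acceptance over all candidate pairs sorted by
ascending distance, each point used at most once — deterministic and
symmetric. The test suite compares this rule against an exhaustive optimal
assignment on small random instances: they agree on the large majority of
instances, and greedy is never better than optimal; the greedy rule is the
documented behaviour, not a claimed optimum. Precision, recall and F1
follow the standard formulas, with explicit zero-denominator conventions
(all-empty agreement scores 1). True negatives are meaningless in point
detection, which is why F1 over matched points is the headline metric.

`density_profile()` stratifies accuracy by local cell density: a kernel
density estimate of the ground-truth centres (unit-mass normal kernels,
σ = 50 px) is split into five bins of **equal density range** — not equal
area and not equal cell count, so bins can be empty. Ground-truth cells
are binned by the density at their own pixel (giving per-bin recall);
detections are binned by the density at the detection pixel (giving
per-bin precision). FPs carry no ground-truth location, so binning
detections by their own position is the only self-consistent choice.

## The synthetic data generator

`simulate_sample()` renders each cell in every plane as a radially
symmetric Gaussian blob whose signed amplitude is linear in defocus —
zero at the in-focus plane, inverting sign across it — with width
`radius × (1 + 0.3 |plane − focus|)`. This reproduces the qualitative
through-focus contrast inversion and defocus blur that the detector
exploits, and nothing else: it is a phenomenological stand-in, not an
optics (PSF) simulation. Additive Gaussian noise comes last.

Two presets define the study axes:

* `sourcelike` — sparse (minimum separation 14 px), high contrast
  (0.45), cell radius 5 ± 0.8 px on 128×128 images: the annotated line.
* `targetlike` — Matérn-style clusters (uniform parents, Gaussian
  offspring with σ = 10 px, ~4 cells/cluster, minimum separation
  17 px) of larger cells (radius 8 ± 1 px) at about an eighth of the
  source contrast (0.06): a dissimilar line growing as dense
  low-contrast sheets in which neighbouring cells touch and little
  background remains — the appearance class on which single-line
  detectors lose recall. Both presets share the imaging parameters
  (background 0.5, noise σ = 0.002), so the domain gap is biological
  (size, contrast, growth pattern), not instrumental.

The target values were chosen once so that a source-trained detector
lands in the regime that motivates adaptation — full precision but
depressed recall on the unseen line, with weak sub-threshold responses
at the missed cells — while keeping enough confident detections for
pseudo-labeling to bootstrap. Two failure modes informed the choice and
are worth knowing about when designing custom presets: if the target
noise floor rivals the faint-cell amplitude, the per-image
standardization amplifies noise until the detector hallucinates peaks,
and iterating on those pseudo-labels amplifies false positives; and if
target cells sit closer together than the peak minimum distance, the
missed cells are structurally unresolvable, pseudo-labels systematically
mark them background, and adaptation *reduces* recall. Both are genuine
properties of the method, not simulator artifacts — the annotated-source
safeguard bounds but does not eliminate them.

What the simulator does **not** model: uneven illumination, debris and
impurities, cell-to-cell appearance correlation, stacking/overlapping
cells in z, camera vignetting, or real defocus optics. Passing the
synthetic end-to-end experiment therefore demonstrates that the pipeline
mechanics work (training converges, pseudo-labeling improves an unseen
dissimilar domain without hurting the source domain) — it does not certify
accuracy numbers on any real cell line.

## The desk-scale reference experiment

`run_domain_experiment()` is the package's end-to-end study at desk
scale, sized so the full pipeline (60 supervised + 60 adaptation epochs)
runs in minutes on one CPU core: 128×128 px, 5 planes, 12 annotated
source images, 8 unlabeled target images, 4 held-out test images per
domain, a depth-3/8-filter detector, mask radius 4 px, and a 10 px
matching radius for scoring (the full-frame convention of 20 px assumes
roughly twice-larger cells). Two peak parameters are likewise scaled to
this geometry: pseudo-label disks of radius 4 px (the full-scale recipe
pairs radius-8 masks with radius-6 pseudo disks; here the mask radius
itself is 4) and a peak minimum distance of 12 px — chosen below the
14 px minimum spacing of simulated cells so that no true pair is ever
suppressed, but above the width of one cell's response plateau so that
ripple on a nearly-flat plateau cannot double-count a cell. All
randomness fans out from one seed via `derive_seed()`.

```{r}
library(brightcell)
res <- run_domain_experiment(seed = 1, verbose = TRUE)
res$target_before$f1   # depressed by the domain gap
res$target_after$f1    # recovered by adaptation
```

## Numerical choices and degenerate inputs

* Peak extraction defines a local maximum on the 8-neighbourhood; a flat
  plateau contributes one peak at its centroid-nearest pixel, and
  min-distance suppression is greedy by descending value with
  deterministic tie-breaks (row, then column).
* Heatmap probabilities are clipped to `[1e-6, 1 − 1e-6]` inside the loss
  to keep the cross-entropy finite in single precision.
* An empty annotation set yields an all-background mask; an
  all-background mask collection makes `class_balance()` return a flagged
  `Inf` ratio rather than an error; an empty heatmap yields zero peaks;
  empty detection/truth sets score 1.0 by the all-empty convention.
* Stacks are stored as 32-bit float TIFF, so unit-scaled intensities
  round-trip at single precision. CSV round-trips of coordinates are
  exact.

## Known limitations

* The network trains on CPU in single precision; large full-frame
  training runs are possible but slow — the package is tuned for
  desk-scale studies and method development.
* The exact layer inventory of the original reduced U-Net is not public;
  the depth-3 reconstruction here matches its described shape (one level
  removed from the canonical U-Net, symmetry kept) but not necessarily
  its filter counts.
* Greedy closest-pair matching can differ from optimal assignment in
  rare, crowded configurations (documented above).
* The simulator's domain gap is one convenient slice of real cell-line
  variability; results on synthetic domains bound nothing on real lines.
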