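---
title: "TongueCaps: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TongueCaps: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tonguecaps)
```

## The problem

Tongue inspection in Traditional Chinese Medicine distinguishes five
tongue-body colors — light red, red, deep red, light white and cyan — whose
chromatic ranges overlap and have no agreed numeric boundaries. This package
implements an end-to-end classifier for segmented tongue photographs (tongue
blob on a black background) built around a capsule network, together with
the full experimental pipeline: deterministic preprocessing, class-balancing
augmentation, a synthetic image generator that stands in for clinical data,
training by margin loss, and one-vs-rest evaluation.

## Preprocessing

Images arrive as 24-bit RGB at arbitrary sizes (clinical acquisition devices
produce, e.g., 1640×2460 and 1480×2220). `resize_pad()` letterboxes each
image: the long side is scaled to the target `L` (bilinear interpolation,
half-pixel-centre convention), the short side is scaled by the same factor
and rounded **half-up** (keeping the aspect error below half a pixel), and
the short axis is padded with black to `L × L`. The content is centred; when
the padding count is odd the extra pixel goes to the bottom/right. The
network then consumes the image in HSV, all three channels on `[0, 1]`
(`rgb_to_hsv()`, hexcone convention via `grDevices::rgb2hsv`); HSV separates
chroma from lightness, which is what the class definitions are about. We use
a single unit-interval dialect everywhere rather than the 8-bit 0–179/0–255
one to remove any ambiguity in the model input.

Brightness manipulation uses the power law `I' = (I/255)^k · 255` with
`k ∈ [0.25, 4]` (`adjust_brightness()`); `k < 1` brightens, `k > 1` darkens.
Results are rounded half-up back to 8-bit. Note an asymmetry forced by
quantization: brighten-then-darken (`k = 0.5` then `2`) round-trips within
one intensity level, but darkening first collapses low intensities to zero,
which no inverse can recover. The augmentation pipeline therefore treats the
two factors as independent variants, never as an invertible pair.

Order of operations: augmentation acts on stored 8-bit RGB images; resizing
and HSV conversion happen at load time (`load_tongue_inputs()`). This keeps
the augmented artifacts viewable and makes the geometric transforms exact
array permutations at native resolution. Whether the power law should act
per channel or on a luminance channel is a genuinely open choice; we apply
it per RGB channel, which commutes with the later HSV value channel only
approximately but matches how such adjustments are usually implemented.

## Balanced augmentation

The training classes are imbalanced (66–244 images per class in the
reference composition). Each class is expanded by an integer multiplier `m`
— the original image plus `m − 1` transformed variants — so the expanded
classes are nearly balanced. The default multipliers
`{light red 4, red 5, deep red 14, light white 5, cyan 6}` are the unique
integers that reproduce the published balanced counts
976/1000/924/980/1032 (total 4912) from the reference training counts.

The variant pool is enumerated canonically (`enumerate_plan()`): identity,
rot90 (counter-clockwise), rot180, horizontal shift (+10 % of width),
vertical shift (+10 % of height), brightness 0.5, brightness 1.5, then
geometric∘brightness composites, then geometric∘geometric composites. Shift
magnitude and rotation direction are conventions (the sources leave them
open); composites are only reached when `m > 7`, i.e. for deep red. The
pair rot180∘rot90 is excluded because it is pixel-identical to
rot90∘rot180, so every plan is pairwise pixel-distinct on non-degenerate
images. The whole expansion is deterministic — re-running it is
bit-identical — because reproducibility of the dataset, not stochastic
regularization, is the goal here; random on-the-fly augmentation is
explicitly out of scope.

## The synthetic tongue generator

Clinical tongue images are private, so the pipeline is exercised on a
seeded generator (`render_tongue()`, `generate_dataset()`). Each image is an
ellipse-like blob on an exactly-black background; the base color is drawn
from a class-conditional H/S/V box; the value channel gets multiplicative
radial shading and a low-frequency ripple; "coating" speckles of a
whitish/yellowish color are stamped at a class-specific density; image sizes
jitter ±10 % around a nominal 120×90 to make the letterbox step do real
work. The five palette boxes are pairwise disjoint and follow the clinical
descriptions qualitatively (light white: desaturated and bright; light red →
red → deep red: increasing saturation, decreasing value near hue 0; cyan:
hue ≈ 0.5). They are configuration, not claims about clinical color ranges.

`hue_probe()` is the generator's separability guard: classify every image by
the nearest palette centre of its mean tongue color. With the default
palette it scores ≥ 0.8 (typically ≈ 1.0), which is what makes downstream
training tests meaningful: a network that cannot learn these classes is
broken. The converse caution also holds — these images are far easier than
clinical ones (no papillae, cracks, moisture, lighting variation, or
ambiguous boundary cases), so passing the end-to-end test demonstrates that
the architecture, gradients and training loop work, not that the model
reaches clinical accuracy.

## The capsule layers

A capsule is a vector-valued unit: its length encodes the probability that
an entity is present, its orientation the entity's attributes. The
primitives in `capsule_core` are:

* `squash(s) = (|s|²/(1+|s|²)) · s/|s|` — compresses lengths into `[0, 1)`,
  preserving direction; the zero vector maps to itself.
* `predict_vectors()` — one learned `D_in × D_out` matrix per (input
  capsule, output capsule) pair: `û_{j|i} = W_{ij} u_i`. The transform is
  per-pair, not shared across input capsules, faithful to the indexing of
  the prediction equation.
* `dynamic_routing()` — logits `b` start at zero; each iteration computes
  couplings `c_i = softmax(b_i)` over the *output* capsules, weighted sums
  `s_j = Σ_i c_ij û_{j|i}`, outputs `v_j = squash(s_j)`, and reinforces
  `b_ij += û_{j|i} · v_j` on all but the last iteration (a final update
  could not affect the returned `v`, and skipping it keeps the
  implementation in lock-step with the brute-force reference used in the
  tests). Three iterations by default, the convention of the original
  capsule-network work; the count is configurable.
* `margin_loss()` — per-class hinge-squared loss with `m⁺ = 0.9`,
  `m⁻ = 0.1`, `λ = 0.5`; zero exactly when the correct capsule is ≥ `m⁺`
  and all others ≤ `m⁻`. Batch reduction is the mean over samples of the
  per-sample class sum.
* `classify_lengths()` — argmax of the capsule lengths, ties to the lowest
  index for determinism.

## The TongueCaps architecture

`tonguecaps_spec()` declares the network: a 7×7 Conv-BN-ReLU stem (3
kernels, 'same' padding), 3×3/stride-2 max pooling, six residual blocks in
three channel stages (64, 128, 256 at full scale), a Primary Caps layer and
a Class Caps layer, finished by a vector-length head. Residual blocks come
in two variants: variant **a** adds an identity shortcut (requires unchanged
channels and stride 1), variant **b** convolves the shortcut (stride `s`,
`k` kernels). The branch is Conv-BN-ReLU → Conv-BN; shortcut and branch are
summed and pass a final ReLU, so a zeroed branch reduces variant a to
`ReLU(x)` — a property the tests exploit.

Two cells of the published layer table cannot hold simultaneously with
their printed kernel counts: a block labelled variant a cannot output 64
channels from 128 kernels, nor 256 channels from a 128-channel input with
an identity shortcut. We resolve both the same way — trust the *output
shape* column, which the downstream capsule dimensions corroborate: the
first stage-1 a-block carries 64 kernels, and the first stage-3 block is
realized with a projection shortcut (variant b at stride 1). The shortcut
projection uses the same 3×3 kernel as the branch. Convolutions carry no
bias: every conv except Primary Caps is followed by batch norm, whose shift
subsumes a bias; Primary Caps is kept bias-free for symmetry.

Primary Caps applies 8 unit groups of 32 3×3 stride-1 convolutions with
**'valid'** padding (forced by the worked 16→14 example), flattens each
unit's map into one vector — 8 capsules of dimension 14·14·32 = 6272 at
full scale — and squashes each capsule so Class Caps receives inputs that
satisfy the capsule length contract. Class Caps has one 16-dimensional
capsule per class (capsule dimension follows the original capsule-network
convention; it is configurable).

`trace_shapes()` propagates shapes symbolically; `count_parameters()` and
`estimate_flops()` give analytic totals. The parameter count is exact
(tested against the instantiated weights). The FLOP estimate is stated
under a documented convention — one multiply-accumulate = one FLOP,
convolutions and capsule transforms only — because published model-size and
FLOP figures for this architecture are not reproducible under any standard
convention and the profiler deliberately does not target them.

## Training

No deep-learning framework is involved: the forward/backward passes are
written in R on top of small Rcpp kernels (im2col/col2im, pooling, direct
convolution for the 3-kernel stem) with GEMMs through BLAS. Two numerical
choices deserve note:

* **Batch norm** uses biased batch variance, ε = 10⁻⁵, and running
  statistics with momentum 0.9 for inference.
* **Routing couplings are detached in the backward pass**: gradients flow
  through the weighted sum and squash but not through the
  softmax/agreement recursion. This is common practice in capsule-network
  implementations; with one routing iteration the gradient is exact, and
  the full-model backward was verified against central differences at
  r = 1 (worst relative error ≈ 10⁻⁶).

Optimizers are plain SGD and Adam (0.9/0.999, ε = 10⁻⁸). Training is fully
seeded — weight init, per-epoch shuffling, and the synthetic data all derive
from one seed — so a run is bit-reproducible. Divergence (non-finite loss)
aborts with a diagnostic rather than continuing silently.

`grid_search_cv()` reproduces the hyperparameter protocol: learning rates
{0.1, 0.001, 0.0001} × {SGD, Adam} × batch sizes {8, 16, 32, 64, 128} — 30
combinations — each scored by k-fold (default five-fold) cross-validated
mean accuracy, with deterministic tie-breaking (smaller learning rate, SGD
first, smaller batch). The trainer is a callable, so the protocol is tested
with planted-optimum mock trainers and is usable with the real one.

## Splits and evaluation

`split_dataset()` partitions per class by a seeded shuffle, either at a
ratio (8:2 by default; train/val counts rounded half-up) or from an exact
per-class count table. The reference clinical composition ships as
`tongue_split_counts()` because no single rounding rule reproduces those
exact printed counts from an 8:2 ratio — they are data, not a formula.

Evaluation tabulates a truth × prediction confusion matrix and collapses it
one-vs-rest per class: accuracy `(TP+TN)/N`, sensitivity `TP/(TP+FN)`,
specificity `TN/(TN+FP)`, macro-averaged without weights (the protocol says
only "average"). A class absent from the truth has undefined sensitivity —
returned as `NaN` with a warning and excluded from the macro mean. The
evaluation loader accepts an optional brightness-jitter vector so a test
set "containing different brightness" can be emulated; its exact clinical
composition is unknown, so the factors are user-supplied configuration.

## Problem sizes used by the tests and the acceptance script

The shipped experiments run on synthetic data at a reduced scale chosen as
a desk-scale study: 64×64 inputs, stage channels 32/64/128 (half the full
width), 130 images per class split 100 train / 30 test, Adam at learning
rate 0.001, batch 25, 10 epochs. Under these conditions the reduced
TongueCaps reaches ≥ 0.85 held-out accuracy (typically ≈ 0.95–1.0), and in
the shipped fixed-seed run it ends with a lower final-epoch margin loss than
its shortcut-ablated twin trained identically — the ablation that removes
every shortcut connection while keeping the same shape trace. Both models
fit the synthetic classes almost perfectly, so the loss ordering between
them is assessed at a fixed seed; it is not a claim about every seed, and
clinical-scale conclusions about the shortcut's value are out of scope. Full-scale clinical results (multi-hour GPU training on
private data) are explicitly out of scope; nothing in this package claims
them.

## Known limitations

* The synthetic generator models color statistics and coating interference,
  not tongue texture; conclusions transfer to the architecture and
  pipeline, not to clinical performance.
* The backward pass's detached routing couplings make the capsule-weight
  gradient approximate for r > 1 (exact for r = 1); training behavior in
  practice is indistinguishable, but second-order methods would need the
  full unrolled gradient.
* JPEG input requires EBImage; the package itself writes PNG only.
* The FLOP profiler counts convolution and capsule-transform
  multiply-accumulates only; elementwise work is excluded by convention.
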