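---
title: "Edge-auxiliary lesion segmentation: model, training protocol, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-auxiliary lesion segmentation: model, training protocol, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Dermoscopy lesion segmentation is hard exactly where it matters: at the
boundary. Pigment regions fade into surrounding skin, and hairs, glue
residue, rulers and ink marks sit on top of both classes. `cclseg`
implements a two-task convolutional architecture that attacks the boundary
directly by predicting the lesion *edge* as an auxiliary task alongside the
mask. The edge ground truth costs nothing: it is derived from the
segmentation mask by a morphological gradient, so no extra annotation is
required.

The network has three parts.

**Encoder.** A truncated residual network: a stride-2 7×7 stem plus
max-pool, then three bottleneck stages of 3, 4 and `conv4_blocks`
(default 23) blocks with widths 256, 512 and 1024. The last stage trades
stride for dilation (stride 1, dilation 2), so the deepest features keep
1/8 resolution — 56×56 for a 448×448 input — instead of 1/16. A pyramid
pooling module then pools these maps at bin sizes 1, 2, 3 and 6, reduces
each pooled map to a quarter of the output width by 1×1 convolution,
upsamples, concatenates with the stage output and fuses with a 3×3
convolution into the shared feature map `F` (128 channels at default
width).

**Cross-connected decoder branches.** Two parallel stacks of three
residual up-blocks decode `F` into a segmentation stream and an edge
stream. Each block is 1×1 (keep width) → 3×3 (bottleneck to 32 channels)
→ 1×1 (back to 128), each convolution followed by batch norm (ReLU after
the first two), a skip-add of the block input, and 2× bilinear
upsampling. After the first stage, each branch's block receives the
element-wise *sum* of its own and the other branch's previous output —
the cross-connection. Edge evidence thereby shapes the mask decoder at
every scale and vice versa.

**Shared multi-scale head.** Each of the three stage outputs gets a
prediction head (3×3 conv + BN + ReLU, then 3×3 conv to one channel); a
fourth map is a direct 1×1 convolution of the last stage. The four logit
maps are upsampled to the input resolution, concatenated, and combined by
a learned 1×1 convolution; one sigmoid is applied at the end. The same
head object serves both branches — sharing the head couples the quality
of the two predictions and adds no parameters.

**Loss.** Each task uses class-balanced binary cross-entropy: for one
image with `N` pixels of which `Npos` are foreground,

$$ l = -\frac{1}{N}\sum_n \big[ w_1\, y_n \log h_n + w_0\,(1-y_n)\log(1-h_n) \big],
\qquad w_1 = N_{neg}/N,\; w_0 = N_{pos}/N. $$

The weights come from each image's own ground truth, so the sparse edge
target (a few percent of pixels) still produces a usable gradient. The
joint objective is $L = \alpha\, l_{seg} + l_{edge}$ with $\alpha = 0.05$
by default: the balance weight multiplies the *segmentation* term, keeping
the two terms in a similar numeric range because the edge target is far
sparser. The configurable sweep $\alpha \in \{0.005, 0.05, 0.25, 0.5\}$ is
exposed under the `loss.alpha` config key.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `input_size` | 448 px | square input side; must be divisible by 8 |
| `width_mult` | 1 | scales every channel count (encoder, decoder, bottleneck) |
| `conv4_blocks` | 23 | depth of the dilated encoder stage |
| `ppm_bins` | 1,2,3,6 | pyramid pooling bin sizes |
| `ppm_out_channels` | 128 | width of the shared feature map `F` |
| `loss.alpha` | 0.05 | task balance, multiplies the segmentation loss |
| `edge_thickness` | 2 px | thickness of the derived edge band |
| `batch_size` / `epochs` | 8 / 30 | optimisation protocol |
| `lr` / `lr_decay` | 1e-4 / 0.9 | Adam initial rate; epoch `e` runs at `lr·0.9^e` |

`width_mult` exists so the same architecture runs at CPU-test size:
`net_config(input_size = 64, width_mult = 1/8, conv4_blocks = 2)` keeps
every structural ratio of the full model (the audit table shows the same
/2, /4, /8, /8, /8 progression) at roughly 1/5000 of the compute.

Edge thickness defaults to 2 px at 448-px resolution: thin enough to be an
edge, thick enough to survive downscaling and give the balanced loss a
non-degenerate positive class. The tiny 64-px test configuration uses
thickness 1 for the same reason in reverse.

## Augmentation and test-time augmentation

Training augmentation composes, in order: horizontal/vertical flips (p =
0.5 each), a centre crop at a scale drawn from [0.75, 1.25] (scales above
1 zero-pad), a rotation drawn from [−20°, 20°], a crop to the mask
bounding box expanded by 50 px (zero-padded where the expansion leaves the
frame; skipped with a message when the mask is empty), and a rigid
moving-least-squares deformation driven by a 4×4 handle grid with
displacements up to 5% of the image side. All of it is compiled into a
*single* coordinate map from the output grid back to the source image and
applied once — bilinearly for the image, nearest-neighbour for the mask.
One resampling means the image/mask pair cannot drift apart, the mask
stays strictly binary, and the edge target is re-derived from the
transformed mask afterwards. The rigid MLS warp fits, per output pixel, a
rotation-plus-translation to the handles by weighted least squares
(weights ∝ inverse squared distance); warping uses the exact backward map
(handles reversed), so zero displacement is the identity and a uniform
handle shift reproduces a global translation exactly — both are tested.

Test-time augmentation uses the six axis-aligned transforms — identity,
three quarter-turn rotations, both flips. The identity is included
explicitly: the prediction of the original image participates in the
average. These transforms are pure index permutations, so their inverses
round-trip bit-exactly, and the six inverted predictions are averaged
pixel-wise. Only the segmentation head is used at test time.

## The compute engine

No deep-learning framework is involved: the package carries its own
dense-tensor engine (RcppArmadillo kernels for convolution via im2col +
GEMM with analytic backward passes, batch normalisation, max/adaptive-mean
pooling, bilinear resizing, and a small define-by-run reverse-mode
autograd in R, plus Adam). Every backward pass is validated against
central-difference numerical gradients in the test suite. Two numerical
choices are worth stating: 1×1 stride-1 convolutions skip patch-matrix
construction entirely (the input already is the patch matrix), and the
backward pass rebuilds each layer's patch matrix instead of caching it —
the per-sample matrix stays cache-hot, which on one CPU core is faster
than retaining every layer's stacked patches between the passes.

Other numerical conventions: predictions are clamped to
`[1e-7, 1 − 1e-7]` inside the loss (degenerate all-one/all-zero masks
then need no special-casing: the vanished class has weight zero and no
pixels); the sigmoid output is kept strictly inside (0, 1) to protect
downstream logarithms from saturated logits; bilinear resizing uses
half-pixel centre alignment; max-pool ties resolve to the first maximum in
column-major order, deterministically; batch-norm running statistics use
momentum 0.1 with the unbiased variance.

## Synthetic data: what it emulates, and what it does not

The generator produces skin-toned images with a single pigmented blob: an
ellipse with a low-frequency radial perturbation (star-convex, hence
always one connected component), darker and browner than the background,
with an illumination gradient, optional boundary blur (the mask's blending
alpha blurred with a Gaussian of configurable sigma), contrast control,
additive noise, and distractor artifacts — dark hair arcs (quadratic
Bézier curves), a bright glue halo, ruler ticks. Artifacts are composited
*after* the mask is fixed: they perturb the image only, mirroring real
annotation semantics (a hair crossing a lesion is not lesion). Lesion area
fraction is kept in [0.05, 0.6] by bounded retries.

An Otsu-threshold baseline spans the intended difficulty range: near-1
Jaccard on crisp high-contrast scenes, degrading monotonically as
fuzziness and contrast worsen — the test suite asserts this ordering. What
the generator does *not* emulate: multi-lesion scenes, colour variegation
within a lesion, specular highlights, vignetting, or the annotation
disagreement of real challenge data. Passing the end-to-end tests
therefore shows that the architecture, losses, augmentation and trainer
interoperate and can recover a learnable signal — not that the model
reaches any particular accuracy on real dermoscopy.

## Ablation configurations

Three constructible variants mirror the ablation structure of the method:

* `seg_only` — encoder + PPM + segmentation subnet; prediction is a 1×1
  convolution + sigmoid on the last stage output (the structural
  baseline).
* `seg_edge` — adds the edge subnet and cross-connections; both tasks use
  the shared minimal 1×1 head.
* `full` — adds the multi-scale aggregation head.

When the aggregation head is ablated the minimal head is the smallest
consistent readout of the last stage; it is shared between branches,
mirroring the sharing in the full head. Parameter counts are strictly
increasing across the three variants, which the tests assert.

## Problem sizes used by the tests and the acceptance script

The full-size architecture is audited once (448-px input, default widths
and depth) by a forward shape audit; that takes a couple of minutes of CPU
and a few hundred MB of memory in inference mode. Everything that trains
runs the tiny configuration: 64-px inputs, `width_mult = 1/8`,
`conv4_blocks = 2`, edge thickness 1, 200 easy synthetic training images,
50 held-out images, 15 epochs, batch 8, flips-only augmentation. The
from-scratch tiny model uses Adam at 1e-3 (the full-scale default of 1e-4
presumes a pretrained 101-layer encoder; a randomly initialised 100k-
parameter model trains an order of magnitude faster). Three seeds are
averaged for the held-out Jaccard of the full model; the ablation
ordering (full ≥ seg+edge ≥ seg-only) is checked against two-seed means
of the two reduced variants, with a 0.03 tie tolerance for seed noise.
The reproduction script (`scripts/acceptance.R`) reports the same
quantities with one run per reduced variant, trading seed averaging for
wall-clock time; its JSON records the sample size behind every number. On easy synthetic scenes the auxiliary edge
task's benefit is expected to be small — the ordering check is therefore
qualitative, ties included, rather than a claim about effect size.

## Open choices made here, and why

* **Fusion operator of the cross-connections: element-wise addition.**
  Every up-block declares the same input width as its output and a
  skip-add; concatenation would double the width and contradict the
  printed channel counts. Addition also makes "remove the cross
  connection" a clean structural ablation.
* **Fusion happens after upsampling.** The previous stage's outputs are
  already at the next stage's resolution, so the two branches' maps agree
  spatially at the fusion point; fusing before upsampling would need an
  extra resize of one operand.
* **No ReLU after the up-block skip-add.** This makes a zero-weight block
  exactly a 2× upsampling, which is both a useful unit-test identity and
  the usual pre-activation reading of residual decoders. Encoder
  bottlenecks keep the conventional post-add ReLU.
* **Logit-space aggregation in the head.** The learned 1×1 combination
  acts on raw per-scale predictions and a single sigmoid is applied last;
  aggregating probabilities and re-convolving could leave the output
  outside (0, 1).
* **Per-image loss weights, batch loss = mean of per-image losses.** The
  balance weights are defined by *a* ground-truth mask, i.e. per image;
  averaging per-image losses keeps images with different foreground
  fractions exchangeable within a batch.
* **Learning-rate decay per epoch.** γ = 0.9 compounded over 30 epochs
  ends near 4e-6, a sane floor; compounding per step would vanish the
  rate almost immediately.
* **Checkpoint selection by validation Jaccard**, the primary metric of
  this task family; without validation data the final weights are kept.
* **Per-image averaging of dataset metrics** (rather than pooling pixels
  globally), the convention of the relevant segmentation challenges;
  degenerate denominators score 1 when vacuously satisfied and are
  flagged in the CSV.
* **Encoder weights are randomly initialised (He).** Nothing is
  downloaded; a checkpoint-loading hook exists for externally supplied
  weights.

## Known limitations

* Double-precision CPU training only; practical problem sizes are the
  tiny-configuration ones above. The full 448-px model runs forward on
  CPU but is not trainable at realistic cost here.
* The decoder is fixed at three up-blocks per branch (8× upsampling), so
  `input_size` must be divisible by 8 and the feature resolution is
  always 1/8 of the input.
* Upsampling is bilinear everywhere; no learned (transposed-conv)
  upsampling.
* No colour-space augmentation, and the per-scale head outputs receive no
  auxiliary deep supervision — only the aggregated predictions are
  trained.
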