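---
title: "Interconnected attention for airway segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interconnected attention for airway segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Airway segmentation on CT slices is dominated by two imbalances: airway
pixels are a small fraction of each slice (well under 10%), and small
terminal branches are a small fraction of that foreground. On top of this,
airway lumina share their intensity range with other bright structures
(vessels, mucus, dense tissue), so intensity alone cannot separate the
classes. This package implements an attention block — AirSeg — that sits
inside the encoder of a UNet-like network and re-weights convolutional
features along five complementary axes, each gated in parallel by a
variance-based embedding field, together with everything needed to train
and evaluate such networks on CPU.

Because R has no deep-learning framework in common scientific use, the
package carries its own minimal stack: convolution, transposed convolution
and pooling kernels in C++ (features are lowered to batch-interleaved
patch matrices so the channel mixing is one BLAS `gemm` per layer, with
fully streamed fills), hand-derived backward passes for every operator,
and Adam. Training switches the convolutions to single precision — the
standard arithmetic for network optimisation — while every other use of
the operators stays in double precision; both paths are deterministic on a
single thread. Every backward pass is validated against central finite
differences in the test suite; the attention operators are additionally
validated against independent naive-loop oracles written in plain R.

## The attention block

All feature maps are numeric arrays of shape `B x C x H x W`
(batch, channels, height, width). Published formulations of such blocks mix height-width-channel and
batch-channel-height-width layouts; the package standardises on the
latter throughout and permutes internally where an
operator needs tokens.

Five operators each produce a gating map with entries in [0, 1]:

* **Image attention (IAM)** — multi-head scaled dot-product attention over
  the `N = H*W` flattened spatial tokens
  (`softmax(Q K' / sqrt(D))`, `D = C/heads`), with dropout on the
  normalised scores and on the output projection during training. A learned
  linear readout averaged over tokens and squashed by a sigmoid reduces the
  refined tokens to a single gate per batch item (`B x 1 x 1 x 1`). A scalar
  per-image gate and a token-level attention mechanism pull in different
  directions; we resolve this by letting the refined tokens
  *drive* the gate while the gate multiplies the incoming features. That
  choice — rather than substituting the refined tokens into the stream — is
  what makes a saturated block an exact identity, a property the test
  suite asserts exactly.
* **Positional attention (PAM)** — per-pixel channel max and mean,
  concatenated and convolved (`k = 7` by default, replicate padding) into a
  `B x 1 x H x W` sigmoid map. The kernel size is a free choice;
  7 is the convention of comparable spatial-attention blocks (CBAM) and is
  exposed in the configuration. Replicate padding is used so that a
  constant field stays exactly constant through the convolution.
* **Semantic attention (SAM)** — global spatial max and mean per channel
  through a shared two-layer MLP, summed, sigmoid; one weight per channel
  (`B x C x 1 x 1`). The hidden width is `C / reduction` with
  `reduction = 16` by default, mirroring the self-channel ratio.
* **Self-channel attention (SCAM)** — the squeeze-and-excitation-style
  bottleneck: global average and max pools through two shared 1x1
  convolutions (width `max(C/ratio, 1)`, ReLU between), summed, sigmoid.
  `ratio = 16` by default.
* **Cross-spatial attention (CSAM)** — by default the conventional reading:
  per-location channel mean and max concatenated and convolved
  (`k in {3, 7}`) into a spatially varying `B x 1 x H x W` map. An alternative literal
  closed form broadcasts the *global* spatial mean and max to every
  pixel, which makes the map spatially uniform; that degenerate reading
  is preserved behind `csam_literal = TRUE` (and is computed analytically,
  since convolving a constant field reduces to a scalar affine map). The
  conventional mode is the default because a spatially uniform map cannot
  "emphasise spatial regions".

### The variance-based embedding (LEM)

For each batch item and channel, with spatial mean `mu` and unbiased
spatial variance, the field

    sigma^2 = (1/(HW-1)) * sum (x - mu)^2 + epsilon
    y       = (x - mu)^2 / (k * sigma^2) + 0.5
    y'      = sigmoid(y)

re-weights the features (`x * y'` by default; additive and hybrid modes are
available). Useful algebra, all asserted by tests: `y >= 0.5` everywhere
because the deviation is nonnegative; `(y - 0.5)` is exactly proportional
to `1/k`; the field is invariant to affine maps of the input up to
`O(epsilon / sigma^2)`; and `max(y - 0.5)` is nonincreasing in `epsilon`.
Defaults are `epsilon = 1e-4` (the middle of the usual stabiliser range:
smaller values amplify noise along with small structures, larger ones
suppress low-contrast detail) and `k = 4` (balanced between the
over-segmentation tendency of `k = 2` and the missed small branches of
`k = 8`); `lem_sensitivity_sweep()` tabulates the field across both
grids.
The formulas contain no free parameters, yet the module is called
learnable; both readings are supported: the default frozen mode evaluates
the closed form, and `learnable = TRUE` makes `epsilon` and `k`
softplus-constrained trainable scalars initialised at those values.
`epsilon` is added after the unbiased normalisation (not grouped as
`k*(var+eps)`); the difference is negligible but the former is the
convention used throughout.

### Composition

Stages run in dataflow order IAM, PAM, SAM, SCAM, CSAM. A nested product
notation for the refined features would list the image gate outermost,
but the executable reading is the dataflow in which each module passes
its output to the next — and stage order makes no measurable difference
in practice. Three fusion modes:

* **sequential** (default): each stage computes its map from the previous
  stage's gated output and multiplies it in, together with the embedding
  field `y'` of the stage input — so every stage is gated as
  `map ⊗ LEM(features)`, and for multiplicative scaling
  `map ⊗ LEM(F) = F ⊗ map ⊗ y'` exactly.
* **sum**: all maps are computed from the block input, combined as their
  normalised mean (keeping the combined map in [0, 1]; the precise
  additive rule is an open design choice, resolved as the mean),
  and applied once together with one embedding factor.
* **parallel**: all maps are computed from the block input and applied as
  one chained product with one embedding factor per enabled stage,
  matching the product form of the refined-feature composition. With
  input-independent maps (and the literal cross-spatial form) sequential
  and parallel fusion coincide exactly; in general they differ.

Disabled stages are exact identities, every gate lies in [0, 1], and in
the fully multiplicative configuration `|F'| <= |F|` holds elementwise.

## Backbones and placement

`build_model()` assembles plain UNet (double-conv blocks) or residual UNet
(conv-conv plus projection shortcut) encoders of configurable depth and
base width, transposed-convolution decoders mirroring the encoder widths,
optional nested skip aggregation (one intermediate node per level — a
light approximation of dense nested skips, which are out of scope), and a
1x1 sigmoid output head. AirSeg blocks sit after the feature extraction of
any chosen encoder level. The default is the deepest level only: image
attention is quadratic in the token count, and at full 256x256 resolution
a first-level placement would need a 65536^2 attention matrix, which no
practical memory budget admits. The output bias is initialised to
`qlogis(0.075)` so that the initial probabilities sit near the expected
foreground prevalence; with overlap losses on highly imbalanced masks this
avoids the flat early regime in which half the image is predicted
foreground. Backbone parameters are drawn before attention parameters, so
a model built without AirSeg is bit-identical to the bare backbone at the
same seed — the property that makes with/without comparisons valid.

## Loss and metrics

Training minimises `w_d (1 - softDice) + w_i (1 - softIoU)` per batch item
(equal weights by default; smoothing constant 1 inside the loss). Reported
metrics use smoothing 0, the convention that two empty masks agree
perfectly, and the exact identity `DSC = 2 IoU / (1 + IoU)` is asserted on
every evaluation. Aggregates are the arithmetic mean and the sample
(n-1) standard deviation across images.

## The phantom corpus

Expert-annotated airway micro-CT corpora are generally proprietary, so
the package generates
branching-airway phantoms with the statistical structure that matters for
the method: a recursive binary tree of anti-aliased tubes whose radius
shrinks by `radius_decay = 0.65` and whose segment length shrinks by 0.72
per generation (so per-generation pixel mass decreases — the small-branch
imbalance is real in the corpus); foreground fraction in the 5–8% range at
the default geometry; a textured background (low-frequency field inside
60–140) with Gaussian noise (SD 12); branch intensities in 150–220; and
eight bright elliptical distractors per image drawn at foreground
intensity but excluded from the mask. The distractors emulate the
airway-lookalike structures (vessels, mucus) that make thresholding fail
on real CT: without them the oracle-best global threshold reaches a Dice
near 0.9 and the task degenerates to thresholding; with them it drops to
roughly 0.75, so a model must use shape and context to do better.
Endpoints are clamped inside the image, which guarantees the mask is a
single connected component. What the phantoms do *not* model: 3D
continuity across slices, reconstruction kernels and beam hardening,
anatomical priors. Passing the learning test on phantoms therefore shows
the architecture and optimisation are sound; it does not certify accuracy
on any particular clinical or preclinical micro-CT corpus.

Augmentation uses exact pixel permutations (flips and 90-degree
rotations) by default so masks stay binary; free-angle rotation with
nearest-neighbour resampling exists behind `augment_rotate()`.

## Training recipe and problem sizes

The reference optimisation recipe is Adam, learning rate 1e-4,
weight decay 1e-5 (classic L2-in-Adam), hybrid Dice+IoU loss, up to 200
epochs with early stopping on a 10% validation split (a held-out fraction of
the training corpus, the standard choice where no separate validation
set exists). The reference batch size is 32;
the CPU-scale experiments in the tests and the acceptance script use batch
2 and 128x128 phantoms with a width-8, depth-4 residual UNet and AirSeg at
the bottleneck, and standardise each input slice to zero mean and unit
variance at the network boundary (well-conditioned inputs reach a given
Dice in a fraction of the optimiser steps) — sizes chosen so a full learning run is a matter of
minutes on one core while leaving every mechanism (all five stages, LEM,
early stopping) exercised. The number of attention heads is 3 in the
reference configuration; head count must divide the gated channel width,
so the width-8/16/32/64 CPU models use 2 heads. At these sizes the smoke
protocol (200 training phantoms, 50 test phantoms) reaches a mean test
Dice of at least 0.80 and clearly beats both the untrained network and the
oracle-best global threshold.

## Numerical choices and degenerate inputs

Sigmoid saturation is exact in double precision (|z| > ~37), which the
identity-gating tests exploit deliberately. Softmax subtracts the row
maximum. LEM requires `H*W >= 2` (the unbiased variance is undefined on a
single pixel) and errors otherwise. Even positional kernels and
cross-spatial kernels outside {3, 7} are configuration errors; a token
sequence of length zero is an error; all-stages-disabled is an error
surfaced per ablation row without aborting the grid. Constant slices
normalise to all-zero images with a warning. Ties in max-pooling and
channel-max backward route the gradient to the first maximising position.
Weight initialisation is fan-in-scaled Gaussian with zero biases (except
the output-prior bias above); all randomness flows through a single seed
per build/run, so checkpoints are bit-reproducible.

## Known limitations

Purely 2D (no volumetric continuity); single-channel input; the ablation
harness reports paired t and Wilcoxon statistics as a descriptive
summary, a deliberately plain choice; the nested-skip style is an approximation,
not full dense nesting; and CPU training at reference scale (256x256,
batch 32, tens of thousands of slices) is out of reach — the package's
problem sizes are chosen for single-core tractability.
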