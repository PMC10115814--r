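---
title: "Dual-branch hybrid segmentation: model, design choices and desk-scale validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-branch hybrid segmentation: model, design choices and desk-scale validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Endoscopic lesion segmentation needs two kinds of information at once: global
context (gastric mucosa is heavily folded, and lesions must be told apart from
fold shadows and specular highlights, which requires long-range comparisons)
and fine spatial detail (the clinically relevant output is a pixel-accurate
boundary). Convolutional encoders excel at the second and struggle with the
first; window-attention transformers are the reverse. This package implements
a hybrid that runs both encoders in parallel on the same image and fuses them
at every scale.

Both branches emit the same feature pyramid: four maps at 1/4, 1/8, 1/16 and
1/32 of the input resolution with C, 2C, 4C and 8C channels (C = 96 by
default, so a 224×224 input gives 56/28/14/7-pixel maps with 96–768 channels).

**Attention branch.** The image is split into 4×4 patches, each linearly
embedded (a 4×4/stride-4 convolution) to C channels and layer-normalized.
Four stages of transformer blocks follow, with patch merging (2×2 neighbor
concatenation, then a linear halving of the combined width) between stages.
Each block computes

    z'  = (S)W-MSA(LN(z)) + z
    z'' = MLP(LN(z')) + z'

where W-MSA is multi-head scaled-dot-product attention restricted to
non-overlapping 7×7 token windows with a learned relative-position bias, and
SW-MSA is the same computation on a grid cyclically shifted by ⌊7/2⌋ = 3, with
an additive −10⁹ mask forbidding attention between tokens that wrap across
image boundaries. Blocks alternate unshifted/shifted; stage depths default to
(2, 2, 6, 2) with (3, 6, 12, 24) heads and MLP expansion 4.

**Convolutional branch.** Five units of (3×3 convolution + batch
normalization + ReLU) ×2 followed by a 2×2 max-pool. Unit widths are
48·2^(i−1); units 2–5 supply the pyramid, so the four shared scales carry
exactly C..8C channels with C = 96.

**DFA decoder** (one per branch). Only the three deepest levels are used —
low-level features contribute little to salient-region localization but
dominate decoder cost. Each level is refined to 48 channels by a
receptive-field block: a 1×1 branch plus three branches with 1×k/k×1
convolution pairs and a 3×3 convolution dilated at rate 3, 5 or 7, merged by
a 3×3 convolution with a 1×1 residual shortcut. The refined maps are
aggregated at 1/8 scale,

    AD1 = concat[ Up2( Up2(F3')·F2' ), Up4(F3') ]     (96 channels)
    AD2 = concat[ Up2(F2')·F1', AD1 ]                 (144 channels)

(products elementwise, product term first in each concatenation), then two
3×3 convolutions and a ×8 bilinear interpolation produce full-resolution
logits.

**FF fusion** (four modules, one per scale). The branch features st_i and u_i
(and, from scale 2 on, the previous fusion output ff_{i−1}, downsampled by a
3×3/stride-2 max-pool) are each refined by a 3×3 convolution to st_i's channel
count; their elementwise (Hadamard) product forms the interaction map b_i;
concat[st_i, u_i, b_i] passes a residual block (two 3×3 convolutions with a
1×1 projection shortcut) back to st_i's width. Threading ff_{i−1} into module
i is the multi-modal mechanism that propagates cross-branch agreement from
fine to coarse scales.

**Gated decoder.** The decoder state starts as ff_4. At each of scales 3, 2,
1 the state is bilinearly upsampled ×2, 1×1-projected to the skip's width
("aligned"), and modulated:

    T_i  = ReLU( W_f(ff_i) + W_up(aligned) )
    up_i = aligned × Sigmoid( BN(1×1 conv(T_i)) )

with a single-channel gate broadcast across channels (a per-channel gate is
available via `model.att.per_channel_gate`). Three convolution units
(C → C/2 → C/2 → C/2, each 3×3 conv + BN + ReLU), a 1×1 logit projection and
a ×4 interpolation give the mask logits.

**Loss.** Each head produces two-channel logits compared to the binary mask
with mean softmax cross-entropy; the total is the convex combination
`L = α·L_ff + β·L_st + γ·L_u` with defaults (0.5, 0.2, 0.3), the weighting
found best in the original study's weight sweep. Single-branch variants train on their
one head.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `model.C` | 96 | pyramid base width; all module widths scale with it |
| `model.unet.base_channels` | 48 | first conv unit width (C/2 keeps the pyramid contract) |
| `model.swin.depths` | 2,2,6,2 | attention blocks per stage (2,2,2,6 selectable) |
| `model.swin.window` | 7 | attention window in tokens; must divide every stage grid |
| `model.dfa.channels` | 48 | refinement width of the aggregation decoder |
| `model.dfa.dilations` | 1,3,5,7 | receptive-field-block dilation schedule |
| `train.learning_rate` | 1e-3 | Adam step size (weight decay 1e-4) |
| `train.loss_weights` | 0.5, 0.2, 0.3 | α, β, γ of the joint loss |
| `train.epochs` / `batch_size` | 300 / 16 | full-scale schedule |

## Design choices where the printed description is ambiguous

These were genuinely open and are fixed here as the package's own choices:

* **Convolution-then-pool unit ordering** in the convolutional encoder: the
  stated output sizes (1/4..1/32 from the last four of five units) force five
  halvings with unit outputs at 1/2..1/32; pooling first would not reproduce
  them. Base width 48 (not 64) makes the shared scales carry C..8C and
  matches the published baseline parameter count far better.
* **Aggregation scale alignment**: as printed, the two concatenated terms of
  AD1 live at different scales; the product term is upsampled ×2 before
  concatenation, the only reading under which AD1, AD2 and the ×8 head
  compose dimensionally.
* **Fusion channel widths**: the printed interaction map dimensions
  (`R^{M×N×P}`, an outer-product shape) contradict "Hadamard product"; all
  three refinement convolutions output st_i's channel count so the product is
  elementwise. The outer-product reading is deliberately not implemented.
* **Gate activation**: the prose says the gate maps to {−1, 1} but the
  operative equation uses a sigmoid; the sigmoid (range (0,1)) is
  implemented. With a zero-initialized gate head the gate is exactly 0.5
  everywhere — a degenerate configuration the tests exploit.
* **Decoder head**: the three head units each carry BN + ReLU as stated;
  applying ReLU directly to logits would clamp them nonnegative and starve
  the softmax loss, so a 1×1 linear projection to the two logit channels
  follows the third unit.
* **Loss orientation**: the printed logistic (`1/(1+e^x)`) decreases in its
  logit, and one loss term lacks its minus sign; as printed the objective is
  unbounded below and untrainable. The standard two-class softmax
  cross-entropy is implemented.
* **Fusion-variant composition**: the parameter table is only consistent with
  the fused baseline *retaining* the original branch decoders as auxiliary
  heads (57.09 M > 53.90 M for the full model, whose branch decoders are the
  much lighter aggregation decoders); that composition is used.
* **Stage depths**: the original study names a tiny pretrained checkpoint whose
  published depths are (2,2,6,2) while printing "2,2,2,6"; the checkpoint
  convention is the default, the alternative a config switch.

## What the synthetic generator emulates — and what it does not

Real gastric endoscopy frames are dominated by smooth pink-red mucosa with
quasi-periodic fold structure, varying illumination, and lesions that differ
from background in hue and texture with irregular but mostly star-convex
outlines. The generator reproduces exactly that coarse structure: a bilinear
low-frequency color field (mucosa palette), a sinusoidal fold pattern of
random frequency/orientation, speckle noise, and 1–3 star-convex blobs with
Fourier-perturbed radius, shifted hue and finer texture. The mask is the
exact union of blob supports, and generation is bitwise reproducible from the
seed (the generator deliberately avoids BLAS calls, whose last-bit rounding
can vary with buffer alignment).

It does **not** emulate specular highlights, instrument shadows, motion blur,
depth-dependent illumination falloff, mucus, or the label noise of manual
polygon annotation. Passing tests therefore demonstrate architectural and
optimization correctness — shapes, gradients, fitting capacity, metric
arithmetic — not clinical segmentation performance; numbers obtained on this
data say nothing about accuracy on real endoscopy images.

Augmentation follows the full stated pipeline: horizontal/vertical flips,
rotation at any angle in [0, 360) (reflect-padded for images, zero-filled
nearest-neighbor for masks), translation up to 10%, zoom 0.9–1.1, and
hue/saturation/brightness jitter on the image only. Jitter magnitudes are
package choices — the original study does not state them. The ~×17.7 augmentation
multiplier of the original training set is a config knob (`aug_factor`),
default 4 at desk scale.

## Numerical choices

* Bilinear interpolation uses half-pixel centers with edge clamping
  (`align_corners = FALSE` convention) everywhere, including the exact
  transpose in the backward pass.
* Batch normalization uses biased variance, momentum 0.1, eps 1e-5; layer
  normalization eps 1e-5; GELU is the exact erf form.
* Max-pool backward routes gradients to the first maximum on ties.
* The shifted-window mask adds −10⁹ to forbidden pairs before the softmax.
* Metric denominators of zero return 1 when the condition is vacuously
  satisfied (empty truth, empty prediction) and 0 otherwise, logged per
  image; reported spreads are population standard deviations (divisor n).
* The dataset-level F1 is the harmonic mean of mean precision and mean
  recall; this reproduces the original ablation table's F1 column from its own
  precision/recall columns to within one unit in the third decimal (the
  printed inputs are themselves rounded to three decimals), and generally
  differs from the mean per-image Dice.
* Adam uses (0.9, 0.999, 1e-8) with decoupled-style L2 added to the gradient
  (weight decay 1e-4), constant learning rate — no schedule is stated in the
  source.

## Desk-scale validation sizes

Tests and the acceptance script run a reduced configuration chosen once:
64×64 images, pyramid width C = 16, one attention block per stage, window 2
(the largest window dividing every stage grid at this size). The end-to-end
fitting check trains the full dual-branch model on four synthetic pairs for
at most 200 Adam steps and requires training Dice > 0.95. Its fixtures draw
lesions at 10–30% image area: at 64×64 the fused head's effective output
stride is 4 pixels, so a lesion near the 2% lower default bound (radius ≈ 5
px) is unresolvable to high Dice for any weights — boundary quantization
alone caps it. Lesions of radius ≥ 9 px span several output-stride cells and
make the check a test of the architecture rather than of the raster.
Full-scale (C = 96) models are built for parameter accounting only; a single
224×224 forward pass of the full dual-branch model takes on the order of
seconds to tens of seconds on one CPU.

## Known limitations

* Parameter counts of the three fusion-bearing variants exceed the original study's
  printed table by a wide margin (the two baselines and the single-branch
  aggregation variant match within a few percent). The printed fusion-module
  description — 3×3 refinement convolutions at native channel widths — is
  arithmetically incompatible with the printed totals: those convolutions
  alone cost more than the implied fusion budget, and the table is internally
  inconsistent about the difference between the fused baseline and the full
  model. The implementation follows the printed equations; the corresponding
  acceptance assertions are left failing rather than reverse-engineering
  undocumented widths.
* No boundary-aware or distance-based loss terms (flagged as future work in
  the original study); no dropout/stochastic depth (rates are not stated; at desk
  scale regularization is counterproductive for the fitting checks).
* Checkpoint import maps a converted state dict by name for the default
  depths only; token and window orderings are internally consistent but not
  guaranteed to match other implementations' orderings element-for-element.
* Training at the full published scale (224×224, C = 96, 300 epochs, batch
  16) is far outside CPU reach; the package's claims at that scale are
  limited to architecture shape, gradient flow and parameter accounting.
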