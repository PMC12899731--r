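---
title: "Methods: attention, box loss, ghost blocks, and the synthetic tray benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attention, box loss, ghost blocks, and the synthetic tray benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feedtray)
```

## The problem

Residual feed left on shrimp feeding trays is the main signal farmers have
for tuning feed dosage: too much residue means waste and deteriorating
water quality, too little means underfeeding. Automating the reading of a
tray image is a small-object detection problem with an unusual profile —
the particles are tiny (most below the COCO small-object threshold), dense,
frequently elongated, mutually adherent, and photographed under uneven
underwater illumination against a repetitive mesh background. `feedtray`
implements the three model components that target this profile, plus the
scaffolding (synthetic data, trainable compact detector, metrics, exact
complexity profiling) needed to exercise and test them end to end on a CPU.

## Three-branch parameter-free attention

The attention mechanism extends the SimAM idea — score each neuron by a
closed-form energy, with no learned parameters — with two extra branches
tailored to small objects. For an input feature map $X \in
\mathbb{R}^{C\times H\times W}$, per channel with mean $\hat\mu$ and
variance $\hat\sigma^2$:

* **Global branch.** The minimal energy of neuron $t$ has the closed form
  $e_t^* = \dfrac{4(\hat\sigma^2+\lambda)}{(t-\hat\mu)^2 + 2\hat\sigma^2 +
  2\lambda}$, so its inverse simplifies to
  $1/e_t^* = \dfrac{(t-\hat\mu)^2}{4(\hat\sigma^2+\lambda)} + \dfrac12$ and
  the weight is $A_\mathrm{global} = \sigma(1/e_t^*)$. Neurons far from the
  channel mean — the statistically distinctive ones — score high. A
  constant channel gives $\sigma(0.5) \approx 0.622$ everywhere.
* **Local branch.** The variance over the 3×3 neighborhood (fixed divisor
  9), $A_\mathrm{local} = \sigma(\alpha\,\sigma^2_\mathrm{local})$: flat
  regions score exactly 0.5, textured ones more. This is the branch that
  separates adjacent particles in dense clusters.
* **Edge branch.** Per-channel Sobel gradient magnitude
  $G=\sqrt{G_x^2+G_y^2}$, $A_\mathrm{edge} = \sigma(\beta G)$, emphasizing
  particle boundaries.

The branches are fused with *data-derived* weights, per channel:
$\omega_\mathrm{global} = \lVert X\rVert_2 / (\lVert X\rVert_2 +
\epsilon)$ and $\omega_\mathrm{local} = \omega_\mathrm{edge} =
(1-\omega_\mathrm{global})/2$, which sum to one by construction. Nothing
is learned anywhere; the mechanism adds exactly zero parameters, which the
test suite asserts.

Defaults and their rationale: $\lambda = 10^{-4}$ (the customary SimAM
regularizer), $\alpha = \beta = 1$ (no established values exist; unit scaling
keeps the two auxiliary branches on the sigmoid's responsive range for
feature maps with O(1) activations, and both are exposed in
`ensimam_config()`). The variance divisor is $M-1$ by default, matching the
reference SimAM implementation, with the population divisor available.
Border handling for the 3×3 pooling and Sobel windows is zero padding with
the fixed divisor 9 of the defining formula, with replicate padding as an
option; under zero padding a constant map keeps its closed-form weights in
the interior but not in the one-pixel border, under replicate padding
everywhere.

Two genuinely open choices had to be settled. First, the channel norm in
the fusion weight: computed per channel (not over the whole tensor), since
the two spatial branches are fused per channel and a whole-tensor norm
would couple unrelated channels. Note the literal $L_2$ norm saturates
$\omega_\mathrm{global}\to 1$ for any non-tiny map (for a unit-variance
$64\times 64$ channel, $\lVert X\rVert_2 \approx 64 \gg \epsilon$); the
literal form stays the default because it is what the formula says, and a
`fusion_norm = "rms"` option divides by $\sqrt{HW}$ for users who want the
fusion to stay adaptive at realistic map sizes. Second, how the fused map
$A$ is applied: multiplicatively, $X \odot A$, following the SimAM lineage.

## Elongation- and orientation-aware box loss

Localization uses a Wise-IoU-style loss with two geometric constraints for
elongated particles. With $L_\mathrm{IoU} = 1 - \mathrm{IoU}$:

$$L = \mathrm{clamp}\left(r \cdot L_\mathrm{IoU} \cdot \gamma,\; 0,\; 1\right)$$

* The **outlier degree** $\beta = d / C$ is the distance between box
  centers over the diagonal of their minimum enclosing box ($0 \le \beta <
  1$ always). Both the distance ratio $d/C$ and its square appear as
  outlier measures in this loss family; the distance ratio is the default
  here and a `beta_squared` switch selects the squared form for
  sensitivity checks.
* The **focusing gain** $r = \beta / (\delta\,\alpha^{\beta-\delta})$
  (defaults $\alpha = 1.9$, $\delta = 3$, the established Wise-IoU v3
  convention). The
  gain is non-monotonic: both near-perfect anchors ($\beta \to 0$) and
  badly misplaced ones (large $\beta$) get reduced gradient gain, so
  training focuses on ordinary-quality anchors. $r$ is treated as a
  constant per step — no gradient flows through it.
* The **orientation modulation** $\gamma$: a pair is *elongated* when
  either box's aspect ratio $\max(w,h)/\min(w,h)$ exceeds $\tau = 2.0$;
  directions are *consistent* when both boxes are wide or both tall (ties
  $w = h$ count as tall). For elongated
  pairs $\gamma = 1-\eta$ if consistent and $1+\eta$ if not, otherwise
  $\gamma = 1$, with $\eta = 0.1$: consistent orientation reduces the
  loss weight, inconsistent orientation increases the penalty.

The clamp to $[0,1]$ is part of the definition and makes the loss flat
outside the clamp interval; the analytic gradient (used by the training
engine and finite-difference-checked in the tests) is
$-r\gamma\,\partial\mathrm{IoU}/\partial B_p$, zero at the clamp
boundaries. One documented literalism: $r = 0$ at $\beta = 0$ zeroes the
loss even for concentric boxes of different sizes. It is kept because it is
what the formula says; an `r_min` floor (default off) is available for
training setups where that matters. In this package's own training loop the
box head decodes cell-relative offsets, so exact center coincidence is a
measure-zero event and the literal form trains fine.

## Re-parameterizable ghost blocks

A ghost module produces $n$ output channels as $m = n/s$ *intrinsic*
channels from a primary convolution plus $(s-1)m$ *ghost* channels from
cheap depthwise $d\times d$ transforms of the intrinsics, concatenated
intrinsics-first. This cuts the multiply-accumulate count from
$n\,c\,k^2hw$ to $m\,c\,k^2hw + (s-1)\,m\,d^2hw$ (`theoretical_cost()`
evaluates both). The cheap transform $\Phi$ is abstract in the general
ghost formulation; the GhostNet convention — depthwise 3×3 + batch norm —
is used, with the re-parameterizable training form adding a norm-only shortcut
branch on the cheap path. Because every branch is linear in evaluation
mode, `fuse_ghost()` folds the norms into the convolutions and sums the
same-support branches into a single depthwise kernel (the shortcut becomes
a center-tap addition); the tests check train/eval-fused agreement to
1e-5 over randomized blocks, strides and kernels. The output combination
is concatenation (the GhostNet convention) by default; an additive merge
(the RepGhost convention) is available via `merge = "add"`.

## The nano detector layout and the complexity budget

The complexity targets are properties of the architecture, not of trained
weights, so the 640-px nano detector is represented *structurally*: an
exact enumeration of every convolution and normalization site with its
spatial size (`nano_detector_spec()`), from which `count_params()` and
`count_flops()` are computed deterministically. The layout is the standard
nano-scale CSP detector this work builds on: stem, four
downsample-plus-split-bottleneck stages, pyramid pooling,
position-sensitive attention stage, PAN neck, decoupled anchor-free head
with distribution-focal regression at strides 8/16/32, width multiple
0.25, depth multiple 0.5, one class. The reconstruction reproduces the
reference baseline budget exactly at this package's conventions: 2,590,019
learnable parameters (2.59 M) and 6.34 GFLOPs at 640 px (with the stock
80-class head the same counter gives 6.51, matching that model's public
6.5 figure).

Counting conventions, stated once: parameters are learnable scalars only
(conv weights and biases, norm scale/shift; the 16 fixed weights of the
distribution-focal decoding conv are excluded); FLOPs are 2 per
convolution/linear multiply-accumulate plus 2 per element normalized by an
affine batch norm — the convention of the thop profiler behind the usual
detector model cards. Pooling, activations, upsampling and the
parameter-free attention count zero, which is also why inserting the
attention changes the GFLOPs column by exactly nothing.

The ghost replacement is specified here by the complexity budget it is
meant to achieve — 2.08 M parameters and 5.50 GFLOPs against the 2.59 M /
6.44 baseline, reductions of 19.7% and 14.6% — rather than by a layer
list, so the mapping is *reconstructed from that budget*. The constraint is tight because early
backbone convolutions are FLOP-heavy but parameter-cheap while late ones
are the reverse: ghosting every downsampling convolution overshoots the
FLOP reduction badly (−22.7%), ghosting only the bottleneck stages
undershoots the parameter reduction. The mapping consistent with both
budget numbers is: every convolution inside the four split-bottleneck
stages (the bottleneck 3×3 pairs and the stage transition 1×1s), the
deepest (stride-32) downsampling convolution, and the two pyramid-pooling
projection 1×1s — each replaced by a ratio-2 ghost module (primary 1×1 at
unit stride, primary 3×3 at stride 2, cheap depthwise 3×3, fusible norm
shortcut). This yields 2.0749 M parameters and 5.43 GFLOPs — reductions of
19.9% and 14.4% against the same counter's baseline. The stem, the earlier
downsamples, the attention stage, the neck and the head stay ordinary.

## The trainable compact detector

The desk-scale training component is a runnable detector built from the
same primitives (conv + norm + SiLU, ghost blocks, the attention site) on
a pure-R engine: im2col convolution through BLAS, manual backward passes,
batch norm with running statistics, Adam. It is deliberately compact — a
three-stage stride-8 backbone (default width 8/16/32), one attention site,
and a single-scale anchor-free head predicting per grid cell the box
offsets, sizes, objectness and class logits. Boxes decode as $c_x = (g_x +
\sigma(t_x))\cdot 8$ and $w = (2\sigma(t_w))^2 \cdot 32$ (maximum 128 px),
the YOLO-family parameterization. The composite loss is $\lambda_1
L_\mathrm{obj} + \lambda_2 L_\mathrm{cls} + \lambda_3 L_\mathrm{loc}$ with
binary cross-entropy for objectness/classes and the modulated IoU loss for
localization; $\lambda = (1, 0.5, 7.5)$, the YOLO-family convention.

Two deliberate simplifications, both documented as this package's own
engineering: target assignment is center-cell (each ground truth trains
the one cell containing its center) rather than a task-aligned assigner —
on the easy, well-separated benchmark scenes a soft assigner changes
nothing measurable and costs substantial complexity; and the attention
weights are treated as constants during backpropagation (gradient flows
through $x$ in $x \odot A$ only), which preserves the parameter-free
property and the forward semantics while keeping the backward pass simple.
Gradient-flow tests assert every learnable parameter still receives a
finite gradient.

Problem sizes for the seeded training benchmark are chosen so the whole
run is a few CPU-minutes: 64 easy synthetic images at 160 px, 30 epochs of
Adam at 5e-3, batch 8. With seed 1 this run takes the total loss from 2.06
to 0.12 and reaches mAP@0.5 ≈ 0.82 on a held-out synthetic split — the
test suite asserts the (much weaker) floor of 0.5. This is a learnability
sanity check of the training plumbing, not a reproduction of any
real-data accuracy figure.

## What the synthetic scenes emulate — and what they do not

The real tray imagery this task is defined on is not publicly available,
so the generator emulates its *reported statistical profile* rather than
its appearance:
roughly 85% of targets below the small-object area threshold
($(32/640\cdot S)^2$ at image size $S$ — the COCO small-object
convention, adopted because the 85% figure comes without a size-bin
definition), roughly 40%
of label boxes with aspect ratio above 2 (the elongation threshold
$\tau = 2$), and strong central concentration of targets. Particles are
rotated capsules whose axis-aligned extent is solved to realize a sampled
label box exactly, so the fractions are controlled by construction
(Bernoulli draws per particle) and only jittered by rasterization and
placement noise; 200 seeded scenes reproduce both fractions within the
±5-point tolerance with a wide margin. Scenes include mesh background,
illumination gradient, adhesion clusters (touching placements), turbidity
blur, unlabeled distractors (bubbles, glints, debris) and unlabeled dark
occluder silhouettes drawn beneath the particles.

What passing these tests shows: the package's statistics, losses and
training dynamics behave correctly on data with the reported statistical
profile. What it does not show: performance on real tray imagery — the
renderer makes no attempt at photometric realism (water color, specular
structure, sensor noise statistics), occlusion by live shrimp is only
crudely mimicked, and real label noise is absent entirely.

Augmentation mirrors the two standard pipelines for this data. The "complete" pipeline
is random crop (boxes retained if ≥30% of their area survives — the
documented threshold), rotation, flip, and brightness/contrast; rotation
is restricted to multiples of 90° so label geometry stays exact without
raster interpolation or loose rotated-corner boxes. The "local" pipeline
crops labeled particles from donor images and pastes them at center-biased
free locations (rejected above IoU 0.1 against existing labels), the
targeted small-object enrichment.

## Numerical choices and degenerate inputs

* Variance divisor $M-1$ fails on a 1×1 channel by construction; this is
  an explicit error, not a silent zero.
* Zero-norm channels give $\omega_\mathrm{global} = 0$ (the $\epsilon$
  guard), handing all fusion mass to the local/edge branches.
* Batch-norm fusion uses running statistics captured at fuse time; fusing
  a never-trained block folds the initialization statistics, which is
  well-defined but pointless, and refusing a double fuse is a warning +
  no-op.
* NMS ties (equal scores) break by input order after the stable
  score sort; IoU exactly at the threshold is kept (suppression requires
  strictly greater overlap).
* Images whose side is not a multiple of 32 are letterboxed bottom/right
  with neutral gray at prediction time, never rejected; boxes are clipped
  back to the original extent.
* Empty inputs: an empty box batch is loss 0 with a warning; an image with
  zero particles is a valid background-only sample; an evaluation set with
  no ground truths is an error (mAP undefined).

## Known limitations

The pure-R engine trains the compact family only — the structural nano
spec is profiled, not runnable, which is sufficient for the complexity
claims but means no full-scale training happens here. The evaluator
implements the 101-point AP convention (and an exact all-point variant
cross-checked in tests) but not COCO-JSON interchange. P/R are reported at
the max-F1 confidence; detection reports in this family rarely state their
operating threshold, so ours is explicit in the output. The synthetic benchmark bounds what any accuracy number here
can mean about real trays; the complexity numbers, by contrast, are exact
architecture properties and transfer as-is.
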