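---
title: "Detecting wheat ears with a lightweight attention network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting wheat ears with a lightweight attention network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earnet)
```

## The problem

Counting wheat ears (the grain-bearing spikes) in field photographs is a
standard phenotyping task: ear density predicts yield, and manual counts do
not scale. Field imagery is hard for detectors — ears are small, dense
(tens per frame), heavily overlapping, and easily confused with leaves and
awns — while deployment targets are often edge devices where model size and
inference cost matter as much as accuracy. `earnet` implements a
single-stage, anchor-based detector designed for exactly this trade-off:
a lightweight asymmetric-bottleneck backbone, a polarized attention block,
a smooth activation, and an overlap-aware box regression loss, with a
synthetic scene generator so that the full pipeline can be exercised end to
end on a CPU with no external data.

Because no deep-learning framework is part of this package's dependency
set, the network engine is self-contained: every layer carries an explicit
forward and backward pass (convolution kernels in C++, the rest in R), and
optimization is plain Adam. All gradients are hand-derived and validated
against central finite differences in the test suite.

## Model

### Backbone

The backbone stacks 15 AsymmBottleneck (ASB) blocks behind a stride-2 stem
convolution. An ASB block is an inverted bottleneck in which the pointwise
expansion is *asymmetric*: of the `exp_size` channels entering the
depthwise convolution, `in_channels` are the block's input carried over
unchanged and only `exp_size - in_channels` are produced by a learned 1x1
convolution. The carried portion costs nothing, which is where the
parameter savings come from. Each block ends with a linear 1x1 projection
to `out_channels`, and a residual connection when stride is 1 and the
channel counts match. `default_backbone_spec()` transcribes the reference
stage table; taps at stages 6, 12 and 15 expose P3 (40 channels, stride
8), P4 (112, stride 16) and P5 (160, stride 32).

Two details of the stage table deserve a note, because the table and the
surrounding prose disagree. The text places the P4 tap at the 13th block,
but the 13th block has stride 2 and 160 channels, which would put P4 and
P5 at the same stride and break the 8/16/32 pyramid the neck requires; the
table's own row labels place P4 at the 12th block (64x64, 112 channels),
and that is what we implement. Similarly the printed input size of the
stride-2 160-channel stage (32x32x112) is inconsistent with the preceding
row's 64x64x112 output; consistent stride bookkeeping forces 64x64 in.

Batch normalization follows every convolution (universal in this block
family, though unstated in the original description), and the stem uses
the same TanhExp activation as the rest of the network.

### TanhExp activation

The network-wide nonlinearity is `f(x) = x * tanh(exp(x))`: smooth,
zero at zero, bounded below by -1, and within 0.01 of the identity for
every input above 1. Numerically we evaluate `tanh(exp(min(x, 20)))`:
`tanh(exp(20))` already rounds to 1 in double precision, so the clamp is
exactly the identity branch and `exp` can never overflow. Because the
engine has no automatic differentiation, the derivative
`tanh(e^x) + x e^x (1 - tanh(e^x)^2)` is hand-coded and
finite-difference-checked.

### Shuffle Polarized Self-Attention

`spsa_block()` divides the channels into `G` groups (default 2); each
group's channels are halved between two polarized branches:

* the **channel branch** collapses space: a softmax over the H*W positions
  of a 1-channel query projection weights a value projection, producing a
  per-channel gate;
* the **spatial branch** collapses channels: a softmax over the globally
  pooled query channels weights the value projection per position,
  producing an H x W gate.

Both gates pass through a logistic sigmoid, so every attention weight lies
strictly in (0, 1), and the reweighted halves are concatenated and mixed
across groups by a channel shuffle (the (G, C/G) transpose permutation).
The original description leaves three things open, which we resolved as
follows: the gate function is the sigmoid (the "boost" step of the
polarized design it builds on); the internal projection width is half the
branch channels ("compress, then boost"); and no normalization layer
follows the gate (exposed design choice — adding one changed nothing in
our CPU-scale experiments and costs parameters). The 1x1 projections carry
no bias so that a zero input produces a zero output exactly — this makes
the zero-pathway invariant testable to machine precision.

SPSA sits between the depthwise convolution and the output projection of
the blocks that carry it — the position the squeeze-excite module occupies
in this block family, which SPSA replaces.

### Neck and heads

A PANet-style neck runs top-down (nearest x2 upsample, concatenate, 1x1
fuse) then bottom-up (stride-2 3x3 convolution, concatenate, 1x1 fuse),
one fusion per junction — the minimal composition consistent with the
drawn structure. Level widths default to the tap widths (40, 112, 160) to
keep the model small. Each head is a single 1x1 convolution to
`3 x (4 + 1 + 1)` channels: per anchor, box offsets (tx, ty, tw, th),
an objectness logit, and one class logit (wheat ear; the class slot is
kept for API generality).

### Box losses

For boxes `a = (x1, y1, x2, y2)` with width/height `w, h`:

* `iou_loss = 1 - |A∩B| / |A∪B|`;
* `giou_loss` adds `|C - A∪B| / |C|` for the smallest enclosing rectangle
  C, so disjoint boxes still receive a gradient;
* `ciou_loss = 1 - IOU + r2²/r1² + αv` additionally penalizes the squared
  center distance `r2²` normalized by the enclosing diagonal `r1²`, and
  the aspect mismatch `v = (4/π²)(atan(w_gt/h_gt) - atan(w/h))²` with
  `α = v / ((1 - IOU) + v)`.

The reference text names α and v but never prints them; we use the
standard definitions from the loss they cite, and hold α constant within a
gradient step (standard practice). The analytic CIOU gradient with respect
to center/size — including the enclosing-box terms — is validated against
finite differences, and all three losses against a pixel-rasterization
oracle at 1000x1000 resolution.

### Assignment, decoding, metrics

Ground-truth boxes are assigned by shape IOU (boxes centered on each
other) to the best of 9 anchors — 3 per level, smallest on P3 — plus any
anchor at or above the 0.5 IOU threshold; a positive lands at the box
center's grid cell, higher shape IOU winning contested slots. Decoding is
the standard YOLO transform (sigmoid cell offsets, `exp`-scaled anchors),
followed by greedy NMS. Evaluation sweeps pooled predictions by descending
confidence, matches greedily (highest IOU, one-to-one, GT index breaking
ties) at IOU 0.5, and integrates the area under the precision envelope —
all-point interpolation, the literal reading of `AP = ∫ P(R) dR`; with one
class mAP equals AP. Greedy matching is pinned as the package's behavior;
the tests verify it agrees with an exhaustive optimal matcher on all
random toy instances with at most five boxes.

## Training

`train_config()` ships the reference recipe as defaults: input 1024,
batch 4, 100 epochs, Adam at 0.01 with weight decay 5e-4, cosine annealing
to 0.2x the initial rate, matching threshold 0.5, with mirror/saturation
augmentation and Mosaic composition on the fly. Two readings were fixed
here: "maximum number of iterations 100" is read as 100 epochs, and the
"cosine annealing parameter 0.2" as the final-to-initial learning-rate
ratio, so the last epoch's rate is exactly `0.2 * lr0` (asserted in the
tests). The composite loss weights (box 0.05, objectness 1, class 0.5)
are engine plumbing, chosen once for stable CPU-scale optimization.

## The synthetic generator

`sample_scene()` renders N ~ Uniform(20, 70) banded, oriented ellipses
("ears", golden with per-ear jitter) over a textured green-brown
background, with a configurable overlap allowance and exact axis-aligned
boxes; everything is a pure function of `(cfg, seed)`. It emulates the
*geometry and statistics* of wheat-field imagery — density, overlap,
scale and aspect ranges, background clutter — and deliberately not its
photometry: no perspective, no illumination model, no real awn or leaf
structure. Tests passing on synthetic scenes therefore demonstrate that
the pipeline (assignment, loss, optimization, decoding, metrics) works
end to end; they say nothing about accuracy on real field photographs,
which would require the real data and training budget this package's
scope excludes.

The `preset = "easy"` configuration (256x256, 6-12 well-separated
high-contrast ears on a plain background) exists for training-recovery
experiments: a width-reduced model (`width_mult = 0.25`, channels rounded
to multiples of 4 with a floor of 8 so the attention halves stay even)
trained for 10 epochs on 64 such scenes reaches mAP@0.5 well above 0.5 on
held-out scenes in a few CPU-minutes. Those problem sizes — 64 training
scenes, 16 validation scenes, 10 epochs at batch 4, and a 50-step
single-image overfit — are the package's chosen desk-scale experiment and
are what the acceptance tests run.

## Numerical choices and degenerate inputs

* Boxes are continuous, half-open, 0-based; areas are `(x2-x1)(y2-y1)`
  with no +1; degenerate boxes (non-positive side) are an error, never
  silently clamped.
* Softmaxes subtract the maximum before exponentiation; `exp(tw)` in the
  decoder is clamped at `exp(10)` to keep early-training boxes finite.
* Batch normalization uses biased batch variance with eps 1e-5 and
  momentum 0.1 running statistics; evaluation mode folds the affine and
  statistics into one fused kernel.
* An image with no ground truth contributes only the objectness term;
  AP over a dataset with zero ground-truth boxes is an error (undefined),
  not a silent 0 or 1.
* `fit_anchors()` keeps empty clusters at their previous center; ties in
  the IOU-distance assignment go to the first (lowest-index) center, which
  with a fixed seed makes the routine fully deterministic.
* Training aborts with a diagnostic on a non-finite loss rather than
  continuing from a poisoned state.

## Limitations

The engine is CPU-bound and double-precision; it is built for
correctness, testability and desk-scale experiments, not throughput —
full-resolution (1024px) full-width training is out of reach here, and
frames-per-second numbers would be meaningless on this substrate, so
none are reported. The synthetic scenes are geometrically but not
photometrically realistic, and single-class. Checkpoints are R RDS files,
not portable across frameworks.
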