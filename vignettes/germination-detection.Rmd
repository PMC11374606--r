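---
title: "Detecting seed germination in soil images: model, objective, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting seed germination in soil images: model, objective, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germdetr)
```

## The problem

Germination trials in substrate soil are harder to read out automatically
than hydroponic trials: the emerging radicle is a thin, low-contrast
structure a few pixels wide, it can burrow into the soil and re-emerge
elsewhere, and the substrate carries distractors -- small stones colored
like seed coats and wood fibers shaped like radicles. `germdetr` implements
a lightweight real-time detection transformer for this setting, together
with the surrounding pipeline: a synthetic scene generator with exact
ground truth, annotation I/O, mild online augmentation, COCO-style
evaluation, and germination-vigor statistics.

Seeds are grown in dishes holding a 7 x 7 grid (49 seeds). Each germinated
seed is annotated with one box covering the seed body plus the visible part
of its radicle, labelled `SROOT` if the root is shorter than the seed body
and `LROOT` if longer (ties break to `SROOT`; the source criterion defines
only the strict cases).

## Model

The detector is a set-prediction (NMS-free) network:

* **Backbone.** The baseline variant uses a ResNet-18-derived backbone
  (two-conv stem variants for the lightweight models), taps C3/C4/C5 at
  strides 8/16/32. The lightweight variants replace strided downsampling
  with **ADown** (average pool, channel chunk, a 3x3 stride-2 conv branch
  and a max-pool + 1x1 conv branch, concatenated) and the residual stages
  with **GELAN** modules (`RepNCSPELAN4` layout: 1x1 transition, channel
  split, two stacked CSP computation blocks whose outputs concatenate
  forward, 1x1 merge).
* **OREPA.** In the final variants the two 3x3 convolutions inside every
  GELAN module are online re-parameterizable blocks: four parallel linear
  branches (origin k x k, 1x1, a 1x1 -> k x k expansion, and 1x1 followed by
  k x k average pooling), each behind a per-channel scaling vector, summed
  and batch-normalized. `orepa_squeeze()` folds the branches and the
  normalization into a single convolution by linear composition; the
  deployed block matches the training block within 1e-4 on any input and
  carries strictly fewer parameters.
* **Hybrid encoder.** One transformer layer (8 heads, FFN 1024) runs on the
  deepest (stride-32) token set; cross-scale fusion is convolutional
  (top-down and bottom-up paths with RepC3 fusion blocks in the baseline
  and GELAN fusion blocks in the lightweight variants).
* **Decoder.** Query selection takes the top 300 encoder tokens by class
  score; their predicted boxes (anchor + learned delta, in logit space)
  initialize the reference boxes. Three decoder layers run self-attention,
  cross-attention, and an FFN, each with per-layer class and box heads that
  iteratively refine the references. In the final variant the attention is
  evaluated in two head groups ("group attention"); this is numerically
  identical to standard multi-head attention and is recorded as a variant
  tag property. Box-delta heads are zero-initialized (boxes start exactly
  at their anchors) and class heads start at a low-probability prior --
  standard detector initialization that also makes desk-scale training
  feasible.

One deliberate deviation from the reference family: decoder
cross-attention attends the encoder-refined deepest level only, not the
concatenated multi-scale token set. Full-pyramid dense attention would cost
roughly 13 GFLOPs at 640 x 640 by itself -- incompatible with the published
cost of any variant -- and the usual remedy (deformable sampling) is a
mechanism this model family does not use. Attending the stride-32 map is
the cheapest faithful alternative and the dish scenes carry no objects that
vanish at that scale for *query initialization*, which still comes from all
three levels.

## The objective

Matching and loss follow the set-prediction recipe. For boxes
$(c_x, c_y, w, h)$ modelled as Gaussians $N(\mu, \Sigma)$ with
$\mu = (c_x, c_y)$ and $\Sigma = \mathrm{diag}(w^2/4, h^2/4)$, the squared
2-Wasserstein distance has the closed form

$$W_2^2(a, b) = \left\| \left(c_{x,a},\, c_{y,a},\, \tfrac{w_a}{2},\,
\tfrac{h_a}{2}\right) - \left(c_{x,b},\, c_{y,b},\, \tfrac{w_b}{2},\,
\tfrac{h_b}{2}\right) \right\|^2 ,$$

and the normalized similarity is $\mathrm{NWD} = \exp(-W_2/C)$ with $C$ a
dataset-scale constant (default 12.8 in box units; the training
configuration rescales it with the image size). The printed form of the
formula divides $W_2^2$ (not $W_2$) by $C$; the construction the term
derives from uses the distance itself, which is also the unit-consistent
choice, so the package implements $\exp(-\sqrt{W_2^2}/C)$ and exposes
`squared_exponent = TRUE` for the literal reading.

The box loss mixes this similarity with generalized IoU:

$$\mathcal{L}_{box} = r\,(1 - \mathrm{NWD}) + (1 - r)\,(1 - \mathrm{GIoU}),$$

with mix ratio $r = 0.5$ by default ($r = 0$ recovers the GIoU-only
baseline objective). The same mix enters the Hungarian matching cost
(`nwd_in_matching = FALSE` switches matching back to GIoU only). Matched
queries also receive an L1 box term; classification is binary
cross-entropy with an IoU-aware positive target (a matched query's target
is its current IoU, so confidence learns to rank localization quality).
Every decoder layer is supervised (deep supervision); the encoder
proposals receive a *dense* auxiliary loss in which every token whose
predicted box overlaps a target at IoU >= 0.3 is a positive -- the proposal
head then becomes useful after very few updates, while the decoder itself
remains strictly one-to-one. The "GIoU 0.5" entry of the reference
training recipe is read as the box-loss gain (`lambda_box = 0.5`), the
only reading consistent with it being listed among training
hyperparameters.

NWD exists because IoU collapses for tiny boxes: at a fixed absolute
center offset, the IoU of two small boxes is far lower than that of two
large ones, while the Gaussian-Wasserstein similarity depends only on the
offset and size mismatch. The test suite asserts this size-insensitivity
directly.

## Reconstructing the published cost ladder

The five variant tags (`baseline_r18`, `adown`, `adown_gelan`,
`adown_gelan_orepa`, `soilcuc`) reproduce the published
parameters/FLOPs ladder: 19.8/19.2/9.1/14.1/14.1 M parameters and
56.9 G (baseline) / 34.9 G (final) FLOPs at 640 x 640, counted on the
train-form model with the factor-2, bias-inclusive convolution convention
(`2 H W (C_{in} K^2 + 1) C_{out}` at the output resolution; linear and
attention layers as twice their multiply-accumulates; pooling,
normalization and activations at zero). Parameters count every trainable
array, so the un-squeezed OREPA branches explain the 9.1 -> 14.1 M jump,
which only the train form can.

The source material prints the ladder but not the internal widths, so the
unstated hyperparameters are fixed by the ladder itself -- the package's
reconstruction procedure, in order:

1. **Baseline.** ResNet-18 stage plan (64/128/256/512, two residual blocks
   per stage, pool-projected shortcuts), 256-wide encoder/decoder, 300
   queries, 3 decoder layers. Free dims settled by the 19.8 M / 56.9 G
   pair: encoder FFN 1024, decoder FFN 932, RepC3 fusion hidden widths
   (128, 126, 126) for the stride-8/16/32 fusion sites.
2. **ADown.** The printed -0.6 M step cannot be produced by substituting
   all three strided downsamplers uniformly (that gives -1.1 M) nor by
   inserting ADown as an extra stage entry everywhere (+1.8 M). The mix
   that reproduces the ladder: substitute the strided conv inside the
   transition block at the first and third transitions, insert a
   standalone ADown followed by a full-width residual block at the second.
   The printed FLOPs for this row (55.6 G) are not reproduced by this
   reconstruction (we measure 56.6 G); the parameter ladder was given
   priority because all subsequent rows chain off it.
3. **GELAN.** Backbone stages become single GELAN modules with
   (c3, c4) = (64, 56), (128, 68), (192, 96), (256, 144); neck fusion
   blocks become GELAN modules (c3 = 128, c4 = 64); two-conv stem. Settled
   by the 9.1 M / 26.5 G pair.
4. **OREPA.** The expansion width of the 1x1 -> 3x3 branch is set per
   pyramid level -- 0.25 at strides 4/8, 2.23 at stride 16, 7.97 at
   stride 32 -- so that the train-form surcharge lands on +5.0 M
   parameters *and* +8.4 G FLOPs simultaneously (the two constraints fix
   the two free expansions; wide re-parameterization branches at deep,
   cheap resolutions are also where they are architecturally harmless).
5. The published table prints a FLOPs difference between the OREPA
   ablation row and the final model (35.8 vs 34.9 G) although the only
   change between them is a loss term, which cannot alter inference cost.
   Both variants therefore share one accounting here, calibrated to the
   final model's printed 34.9 G.

```{r ladder, eval = FALSE}
for (v in c("baseline_r18", "adown", "adown_gelan", "soilcuc")) {
  m <- build_model(model_spec(variant = v))
  cat(v, count_params(m, in_millions = TRUE), "M,",
      count_flops(m, in_g = TRUE), "G\n")
}
```

## The synthetic scene generator

No public dataset exists for this acquisition setting, so the package
generates its own scenes with exact truth: a dark substrate-brown
background with band-limited multi-scale noise, elliptical seeds jittered
around their dish-grid centers, curved radicles drawn as disc chains
whose length is a ratio of the seed length, stones colored near the seed
coat and fibers colored near the radicle as distractors, and optional
burial (a contiguous stretch of the radicle alpha-blended into the soil).
Annotations are derived from the stored truth: one box per germinated
seed over the seed body plus the *visible* radicle extent, with the class
from the *true* root length -- mirroring an annotator who watched the dish
and knows the root continues under the soil.

Defaults are the acquisition conditions the detector targets: 640 x 640
training resolution (the camera's native dish crop of 1,840 x 1,800 is
available through `image_size`), a 7 x 7 grid, germination fraction 0.5,
root-length ratios 0.25-2.5 (mixed SROOT/LROOT), burial probability 0.3,
6 stones and 4 fibers per dish, 6 px jitter. Where the source setting
prescribes a number (dish layout, resolution, class rule, split ratios)
the generator uses it; the remaining levels are fixed once at values
typical for substrate-soil germination imagery and are not tuned.

What the generator does *not* emulate: real soil granularity and specular
reflections, hypocotyl/cotyledon stages, seed-coat texture variation,
moisture gradients, and camera noise beyond white + band-limited noise.
Tests passing on these scenes therefore demonstrate the pipeline's
correctness (geometry, bookkeeping, losses, statistics, trainability) --
not field accuracy on real dishes.

## Training, and what the smoke run shows

`train()` runs AdamW on the package's own reverse-mode autodiff graph
(convolution/pooling kernels in C++, everything else in R). The default
configuration mirrors the reference recipe -- 100 epochs, batch 4,
640 x 640, box gain 0.5, workers 4, cache off, no pretrained weights --
and is the path a GPU-scale reimplementation would calibrate against; it
is not exercised at full scale here.

The smoke run (`smoke_train()`) is the package's end-to-end trainability
check: 50 easy early-germination scenes (3 x 3 dishes at 96 x 96 px, all
seeds germinated, radicles shorter than the seed, no burial or
distractors), a width-reduced final-variant model (scale 0.125, 15
queries, 1 decoder layer), 3 epochs at batch 1 with learning rate 1e-2.
Under the pinned seed this reaches mAP@0.5 around 0.8 on a held-out
synthetic split in about a minute of CPU time, and the epoch losses
decrease monotonically. The problem sizes were chosen so the whole check
stays a smoke test: they demonstrate that the assembled system -- scene
generation, augmentation, forward pass, matching, the NWD+GIoU objective,
backpropagation, optimization, post-processing and evaluation -- learns
end to end, nothing more.

## Evaluation conventions

* Greedy confidence-ordered, class-aware one-to-one matching; a detection
  whose only qualifying overlap is an already-consumed ground truth is a
  "repeated" false positive -- kept separate in the error taxonomy
  (missed / false alarm / repeated) but still an FP in precision, recall,
  and AP, so the standard formulas stay standard.
* AP uses the 101-point interpolated precision envelope; mAP@0.5:0.95
  averages the IoU grid 0.50, 0.55, ..., 0.95 (the integral definitions
  do not pin a discretization; this is the COCO convention). The
  implementation is checked against a brute-force envelope oracle on a
  thousand random small cases.
* With no predictions at all, precision is defined as 1 and recall as 0.
* The germination index follows the printed formula
  $\sum_t G_t / D_t$ (newly germinated seeds weighted by the inverse of
  their day), not the accompanying prose ratio, which conflicts with it;
  the formula is the standard vigor index. `detections_to_series()`
  resolves repeated detections of one seed by snapping detections to the
  nearest dish-grid cell (ties to the lower cell index), latching
  germination, and counting each cell once -- so the error mode of a root
  re-emerging elsewhere never double-counts a seed.

## Numerical choices and limitations

* Batch-norm statistics fold into the squeezed OREPA convolution and
  `reparameterize_model()` fuses every conv + norm pair; equivalence
  tolerances are 1e-4 per block and 1e-3 for the full model (float
  accumulation-order differences only; measured drift is ~1e-14).
* SiLU activation everywhere in the convolutional trunk (the deployment
  family's convention; the source never names one), ReLU inside MLP heads.
* Ties: `label_root_class` breaks equal lengths toward SROOT; equidistant
  detections snap to the lower grid-cell index; query selection breaks
  score ties by token order.
* The smoke-scale results say nothing about accuracy on real soil
  imagery; the published headline accuracies are tied to an unpublished
  dataset and full-scale GPU training, both outside this package's scope.
* Training runs single-process; `workers` is accepted for configuration
  compatibility and logged, not parallelized.
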