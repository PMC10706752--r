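---
title: "Methods: the attention-based image sequence analyzer and its pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the attention-based image sequence analyzer and its pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the modelling and implementation decisions behind
`abisa`: the classifier, the tiling and filtering rules, the synthetic data
the package is validated on, and the numerical conventions. It is the place
to look when a default seems arbitrary — each one is explained here once.

## Problem setting

Odontogenic keratocysts (OKCs) recur after surgery in a substantial fraction
of patients, and recurrence correlates with histological features — most
prominently a band of subepithelial hyalinization beneath the cyst
epithelium. The pipeline stratifies a whole-slide image (WSI) into
*recurring* vs *non-recurring* risk in three stages: tile the slide, classify
each informative tile, and threshold the fraction of recurring tile calls.
The package assumes H&E-stained slides scanned at a single high-resolution
level; it does no stain normalization and no artifact/blur detection (slides
with such problems are assumed to have been excluded upstream).

## Tiling and white-tile rejection

Tiles are cut from the highest-resolution level on a floor grid:
`n_rows = floor(H / tile_size)`, `n_cols = floor(W / tile_size)`, partial
edge tiles discarded. The classifier needs fixed-size inputs, and the floor
policy keeps the tile count arithmetic exact (a 126,976-pixel square at tile
size 2048 gives exactly 62 x 62 = 3844 tiles).

A tile is kept only when both information statistics pass:

* **entropy** ≥ 4.0 bits — Shannon entropy of the 256-bin histogram of the
  8-bit grayscale rendering (BT.601 luma `0.299 R + 0.587 G + 0.114 B`,
  rounded to the nearest bin). Glass/background is nearly uniform and scores
  well under 1 bit; tissue texture spreads over many gray levels and scores
  above 5 in practice. The maximum possible value on 8-bit data is 8 bits.
* **variance** ≥ 100.0 — population variance of the same grayscale values.

Failing *either* test discards the tile (background can be low-entropy, or
low-variance, or both). Both thresholds are configurable in
`tile_filter_config()` and are recorded on the manifest, because they are the
one place where a scanner with unusually flat illumination might need
retuning. Entropy and variance are permutation-invariant in the pixels, so
the filter is a pure function of the tile's histogram; re-tiling a slide is
byte-reproducible.

## The classifier

`build_abisa()` composes, for a 64 x 64 x 3 input on the 0..255 scale:

1. **Input standardization.** Pixels are scaled to [0, 1] and standardized
   per channel with dataset statistics fitted at the start of training
   (mean, variance and an accumulation count — 7 non-trainable values).
   Model summaries conventionally include such statistics in the *total*
   parameter count, and `count_parameters(trainable_only = FALSE)` follows
   that convention.
2. **Patch extraction.** Non-overlapping 6 x 6 patches, row-major over the
   `(64 %/% 6)² = 100`-patch grid; the outer 4-pixel margin not covered by
   the grid is ignored. Each patch is raster-flattened (RGB interleaved per
   pixel) into a 108-vector.
3. **Patch encoder.** A shared linear projection to 64 dimensions plus a
   learned positional embedding per patch index.
4. **Transformer blocks (x4).** Multi-head self-attention (4 heads, per-head
   query/key/value width 64, dropout 0.1 on the attention probabilities,
   output projected back to 64), a skip connection adding the block input,
   then layer normalization. The per-head width equals the embedding width
   here; the two are independent knobs in `model_config()`.
5. **LSTM.** A 32-unit LSTM runs over the 100 patches in their row-major
   spatial order with zero initial states and returns the *full output
   sequence* — one 32-vector per patch — so spatial layout information
   survives into the head.
6. **Head.** Layer normalization over the 32-wide outputs, flatten to 3200,
   dropout 0.5, dense 2048 (GELU), dense 1024 (GELU), dense 2, softmax.

`build_standard_vit()` is the ablation baseline: identical trunk, no LSTM;
after the final block the 64-wide sequence is layer-normalized and flattened
(6400) straight into the same head. Because the LSTM narrows the per-patch
width from 64 to 32, the ABISA flatten is half as wide and the first head
layer — by far the largest tensor — halves: 8,947,721 vs 15,488,969 total
parameters, a 42% reduction for the hybrid.

**Block layout.** Textbook vision-transformer blocks append a position-wise
feed-forward sub-block after the attention; the reference architecture this
package reproduces does not, and the evidence is arithmetic: with
attention-only blocks (and the 7 standardization statistics) both
architecture totals come out at exactly the reference values above, while
any FFN variant overshoots by tens of thousands of parameters. The default
is therefore `use_block_ffn = FALSE`; setting it to `TRUE` builds the
textbook layout (`[128, 64]` GELU sub-block with its own skip and layer
norm) for comparison, and the test suite pins the closed-form totals of both
layouts.

### Training

Sparse categorical cross-entropy over integer labels {0 = non-recurring,
1 = recurring}, Adam with decoupled weight decay (learning rate 1e-4, weight
decay 1e-3, β₁ = 0.9, β₂ = 0.999, ε = 1e-7), batch size 20, 25 epochs by
default. Decay applies to weight matrices and embeddings, not to biases or
layer-norm parameters — decaying a layer-norm gain fights the normalization
itself. When validation data are supplied, the best-validation-loss epoch's
weights are restored at the end (`early_stop_on_val`), reflecting the usual
practice of stopping where validation loss turns upward. Everything random —
initialization, batch order, dropout masks, augmentation draws — hangs off
the single seed in `train_config()`, and runs are bit-reproducible within
one BLAS/software environment.

Initialization: Glorot-uniform kernels, zero biases except a unit
forget-gate bias in the LSTM, orthogonal per-gate LSTM recurrent blocks,
uniform(-0.05, 0.05) positional embeddings, unit layer-norm gains.

### Implementation notes

No deep-learning framework is involved: forward passes and hand-derived
backpropagation live in `R/nn.R`, with two C++ kernels (RcppArmadillo) for
the per-sample, per-head attention products and the elementwise optimizer
step — the two spots where R-level temporaries dominated the runtime. A
finite-difference gradient check over every parameter tensor of three model
variants guards the backward pass; analytic key-bias gradients are exactly
zero (a constant added to every key shifts all attention scores in a row
equally and cancels in the softmax), and the test asserts that too.

Numerical conventions: softmax rows are stabilized by subtracting the row
maximum; layer normalization uses ε = 1e-3 on the population variance;
dropout is inverted (masks scaled by 1/(1-p) at training time, nothing at
inference); log-loss probabilities are clipped at 1e-15; GELU is the exact
`x·Φ(x)` form with derivative `Φ(x) + x·φ(x)`.

## Dataset pipeline

`split_dataset()` applies the 70-10-20 rule with test and validation sizes
rounded to the nearest integer and train taking the remainder — under this
rounding 508 labelled tiles yield a 102-tile test partition. Stratification
(the default) apportions each partition across classes by largest remainder,
keeping per-class proportions within one item. Splits are deterministic in
the seed and always disjoint and exhaustive. Stratification is at tile
level; the package does not group tiles by source slide, so when several
tiles come from one physical slide, related tiles can appear on both sides
of a split — a known limitation to keep in mind with real data.

Augmentation (`augment_config()`) is sampled on the fly per training batch,
never applied to validation or test data: rotation uniform in ±20°, shifts
uniform in ±10% of image size, shear factor uniform in ±0.2, per-axis zoom
uniform in [0.8, 1.2], horizontal flip with probability 1/2. The affine
transforms are applied by inverse mapping with bilinear interpolation;
out-of-bounds samples take the nearest edge pixel (constant fills would
inject artificial background that the white-tile statistics downstream of
augmentation would mis-read). `resize_tile()` uses the same sampler with
half-pixel centre alignment; the test suite cross-checks it against
EBImage's bilinear resampler.

## The synthetic data generator

Real OKC slides are not distributable, so the package validates itself on
synthetic data built to exercise every interface:

* **white tiles** — value ~250 with sparse ±1 jitter: under 1 bit of
  entropy and variance under 10, far below both filter thresholds;
* **non-recurring tiles** — seeded smoothed uniform noise blended across an
  H&E-like palette (eosin pink `(240, 168, 200)` to hematoxylin purple
  `(112, 70, 148)`) plus per-channel speckle of ±24 intensity levels;
* **recurring tiles** — the same texture plus a smooth horizontal band of a
  brighter, higher-saturation pink `(244, 100, 136)`, spanning 22–40% of
  the tile height and centred in the middle portion, with linearly tapered
  edges — a deliberately minimal emulation of a hyalinized subepithelial
  band.

The palette and speckle amplitudes were chosen so that tissue tiles clear
the default filter thresholds with a wide margin (minimum observed variance
131 over 300 seeds at three tile sizes, against the 100 threshold) while
white tiles stay far below, and so that a trivial rule — thresholding the
mean saturation of the central rows — already separates the classes. That
separability is asserted by a test, because it is what makes the end-to-end
training property meaningful: if a one-feature rule can solve the task, a
9M-parameter model failing it would indicate an implementation bug, not a
hard dataset.

The flip side: passing on this generator demonstrates that the machinery —
tiling, filtering, splitting, training, inference, aggregation — is wired
correctly and can learn a localized chromatic motif. It says nothing about
accuracy on real histology, where the discriminative features are subtler,
multiple, and entangled with staining variation. Every generator output is
deterministic in its seed, and generation never perturbs the caller's RNG
stream.

## Slide-level aggregation

`decide_slide()` calls a slide recurring when
`n_recurring / n_classified ≥ threshold` with the default threshold 0.15.
The comparison is inclusive (the boundary case counts as recurring — the
conservative choice for a screening aid), the denominator is all classified
(informative) tiles, and the decision is monotone in the recurring count. A
slide with no informative tiles is an error, not a silent non-recurring
call. Smaller slides may warrant a lower threshold; that is exposed as a
per-run override in `aggregation_config()` rather than an automatic rule,
since no principled size-to-threshold mapping is established.

## Metric battery

`compute_metrics()` derives the full report from a 2x2 confusion matrix with
classes ordered (0 = negative/non-recurring, 1 = positive/recurring):
per-class precision/recall/F1 with macro and support-weighted averages,
accuracy, balanced accuracy, MCC, Cohen's kappa, positive-class Jaccard,
specificity, sensitivity, Youden's J and the G-mean; Brier score, log loss
and ROC AUC additionally require per-sample scores and are reported as `NA`
(never silent zeros) without them. Conventions: zero-denominator precision
or recall is 0 with a warning; MCC is 0 when a marginal is 0; values are
kept at full precision, with `format_report()` rounding to 2 decimals for
display only. One worked identity worth remembering: support-weighted recall
always equals accuracy, and the suite asserts it across a thousand random
matrices against a brute-force oracle that recomputes every metric from the
enumerated labels. The G-mean of a report with sensitivity 1.00 and
specificity 0.96 is √0.96 = 0.9798, which rounds to 0.98 — 2-dp displays of
such a report that show 0.97 have rounded an already-rounded intermediate.

`reconstruct_confusion_from_report()` inverts a printed classification
report (per-class support and recall) back to the matrix; for a binary
problem the reconstruction is exact whenever `recall × support` is integral,
and ambiguous inputs raise an error naming the nearest integer candidates.

`roc_curve()` places thresholds at the distinct scores (ties move along the
curve diagonally, so constant scores give AUC 0.5) and integrates by the
trapezoidal rule; it is cross-checked against pROC.

## Problem sizes in the test suite

The suite validates the learning property at a deliberately compact scale:
400 training tiles (200 per class, 64 px), 10 epochs at batch 20 and
learning rate 1e-4, a 100-tile held-out set, and 10 x 10-tile synthetic
slides at recurring fractions 0.30 and 0.02 for the slide-level calls —
sizes at which the full run finishes in minutes on one CPU core while still
exercising every stage at the real architecture size. Exact worked examples
(parameter totals, grid and split arithmetic, the reconstructed confusion
matrix) run at full fidelity since they cost nothing.

## Known limitations

* Binary classification only; no multi-class generalization of the metrics.
* No slide-grouped splitting, stain normalization, or artifact detection.
* Tile predictions are aggregated by count only — no spatial smoothing,
  heatmaps, or multiple-instance learning.
* The synthetic generator encodes a single discriminative motif and is a
  test harness, not a histology simulator.
* Pyramidal input support covers multi-page TIFF (largest page = highest
  resolution); vendor-specific WSI containers need conversion upstream.
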