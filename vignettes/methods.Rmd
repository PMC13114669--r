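---
title: "Triple-branch ultrasound lesion segmentation: model, training and explainability methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triple-branch ultrasound lesion segmentation: model, training and explainability methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`busseg` implements a hybrid segmentation network for grayscale breast
ultrasound together with everything needed to study it quantitatively on a
single CPU: a boundary-aware composite loss, a speckle phantom generator, a
cross-validation and ablation harness, per-image segmentation metrics with a
paired statistical battery, and a quantitative explainability (XAI) layer.
This vignette documents the model and every numerical decision that is not
visible from the function signatures.

## The model

The encoder is CNN-anchored and hierarchical. A 7×7 stride-2 stem maps the
grayscale input to the first channel width; four residual stages (basic
blocks: two 3×3 convolutions with a projection shortcut where shape
changes) produce features at 1/2, 1/4, 1/8 and 1/16 of the input
resolution with widths `level_channels` (default 64/128/256/512, stage
depths 3/4/6/3). At every level the CNN stage output is fed, in parallel,
to

* a **Visual State Space (VSS) block** — layer norm, channel expansion by
  `expand`, a depthwise 3×3 convolution with SiLU, four selective scans
  over the flattened token grid (down/up columns, forward/backward along
  rows) whose outputs are averaged, an output layer norm, multiplicative
  SiLU gating, projection back to the level width, and a second sublayer
  with an MLP of ratio `mlp_ratio`. The scan is the selective (S6)
  recurrence `h_t = Abar_t h_{t-1} + Bbar_t x_t`, `y_t = C_t h_t + D x_t`
  where the per-token step size Δ (through a softplus-activated low-rank
  projection, `dt_rank = ceiling(inner/16)`), B and C are linear
  projections of the token, each scan direction carrying its own
  projections, and `Abar = exp(ΔA)`,
  `Bbar = (ΔA)^{-1}(exp(ΔA) − I)ΔB` by the zero-order hold. The factor
  `(e^z − 1)/z` is evaluated with `expm1`, which is continuous through
  `z = 0` (limit `Bbar = ΔB`), so no hard switching threshold is needed.
  `A` is a learned per-channel diagonal initialized to `−(1..d_state)` and
  kept negative through a log parameterization.
* a **pre-norm transformer block** — learned positional embeddings per
  level, multi-head self-attention (`heads_per_level`, default 2/4/8/16),
  an MLP of ratio 4 with GELU, and dropout 0.1 on the attention output
  projection and the MLP. Dropout is deliberately not applied to the
  attention weight matrices; the projection/MLP dropout is what the
  Monte-Carlo uncertainty machinery samples.

The three branch maps are combined by the **adaptive feature fusion
module**: channel concatenation, 1×1 convolution back to the level width,
global average pooling, a two-layer MLP with reduction ratio `r = 4`, and a
softmax producing one scalar weight per branch per sample; the fused map is
the weighted sum and feeds the next CNN stage. Ablation alternatives
(concatenation + 1×1 convolution, squeeze-excitation gating, plain
averaging) sit behind the same interface. The decoder is a U-Net++-style
dense nested decoder: nodes `X(i,j)` (`i + j ≤ 3`) receive the upsampled
`X(i+1, j−1)` concatenated with all `X(i, 0..j−1)`; node widths equal the
encoder width of row `i`, each node applies one 3×3
convolution–GroupNorm–ReLU, upsampling is bilinear, and a 1×1 head on
`X(0,3)` produces the logit map, which is upsampled to input resolution.
The plain decoder used by the `no_dense_decoder` ablation keeps only the
classic single chain.

Normalization inside convolutional blocks is **GroupNorm** with at least
four channels per group (capped at eight groups): it is batch-size
independent and deterministic, which the reproducibility contracts require,
and well-conditioned group statistics keep the network smooth as a function
of its input — with one channel per group the group variance of a small
feature map collapses often enough to create sharp cliffs that degrade both
optimization and path-integrated attributions. The logit head bias is
initialized to −2 so that the initial foreground probability (~0.12)
roughly matches the lesion area fraction; all other parameters use
fan-in-scaled Gaussian initialization under a single seed.

### Why the package ships its own autodiff

No deep-learning framework is available in the target environment, so the
package contains a small tape-based reverse-mode engine
(`R/autograd.R`, `R/ops.R`) over dense arrays with compiled kernels
(`src/kernels.cpp`) for the im2col convolution, depthwise convolution, the
selective scan (forward and hand-derived backward), fused attention,
layer/group normalization and the SiLU/GELU activations. Every kernel's
gradient is verified against central finite differences in the test suite.
Evaluation-mode forward passes skip tape recording entirely.

## Loss

The training objective is the boundary-aware composite loss
`L = λ1·L_BCEw + λ2·L_Dice + λ3·L_boundary` with `λ1 = λ2 = λ3 = 1`:

* `L_BCEw`: pixelwise binary cross-entropy with weight 3 on the
  morphological boundary band of the target (dilation minus erosion with a
  7×7 square kernel, zero padding on both operations) and weight 1
  elsewhere, normalized by the total weight so its scale is comparable
  across lesion sizes.
* `L_Dice`: soft Dice over the image with smoothing constant 1.
* `L_boundary`: mean unweighted BCE restricted to the band (0 when the
  band is empty). The literature names this term without writing its
  formula; restriction of the BCE to the band is the most direct reading,
  kept separate from the weighted term so the two can be combined or
  disabled independently (`no_dbr_loss` sets `λ3 = 0` and equal pixel
  weights, i.e. plain BCE + Dice).

Training evaluates the loss on logits via the numerically stable
`max(z,0) − zt + log1p(exp(−|z|))` form; probabilities are clamped at
`1e-7` wherever BCE is computed from probabilities directly.

## Phantom generator

The generator emulates the properties of breast-ultrasound B-mode images
that the network and the metrics are sensitive to, without claiming
acoustic realism: a smoothly varying echogenic background (coarse uniform
grid, bilinear upsampling, mean ≈ 0.75), star-convex hypoechoic lesions —
ellipses whose radius is modulated per angle by a low-order random Fourier
series of unit RMS scaled by `boundary_irregularity` (default 0.15) — with
interiors darkened multiplicatively by `lesion_contrast` (default 0.45),
optional soft posterior shadow bands under a lesion
(`shadow_probability`, default 0.3, mimicking the attenuation-shadow
failure mode of real scans), and fully developed multiplicative speckle
drawn from a unit-mean gamma distribution with shape `speckle_scale`
(default 6). The lesion radius is corrected by `1/sqrt(1 + irregularity²)`
so the realized mask-area fraction tracks the requested range; lesions are
rejected on overlap or canvas overflow with a bounded retry budget. The
image is min–max normalized to [0, 1].

What the phantoms do **not** model: beamforming artifacts, Cooper's
ligaments, heterogeneous fibroglandular texture, BI-RADS-realistic lesion
morphology, operator variability. Passing the end-to-end criteria on
phantoms therefore demonstrates that the architecture, loss, training loop
and analysis pipeline are correct and well-conditioned — not that the
miniature model would transfer to clinical data.

Everything is a deterministic function of `(spec, seed, index)`; datasets
are written as 8-bit PNGs (masks 0/255) with a `id,image_path,mask_path,fold`
manifest, folds assigned round-robin (image-disjoint, sizes differing by at
most one).

## Training protocol

AdamW (decoupled weight decay 1e-4), batch size 16, cosine annealing with
warm restarts stepped per epoch (`T0 = 20`, `Tmult = 2`), initial learning
rate 1e-4, up to 100 epochs with early-stopping patience 30, and selection
of the lowest-validation-loss parameters — validation being the held-out
fold itself (no inner split). Augmentation: horizontal flip (p = 0.5),
rotation within ±15°, translation up to 5% of the side and isotropic scale
0.9–1.1 (mild affine defaults chosen to keep lesions on canvas), identical
transforms for image (bilinear) and mask (nearest, re-binarized). Per-fold
seed = base seed + fold, so folds are reproducible yet decorrelated.

The **miniature protocol** (`mini_model_config()` + `mini_train_config()`)
is the package's desk-scale experiment: channels 8/16/32/64, heads
1/2/2/4, `d_state = 8`, one residual block per stage, 64 px phantoms, 160
images in 2 folds, 5 epochs, initial learning rate 1e-3 with a 15-epoch
cosine cycle. The higher learning rate and short schedule are what a small
model on a small, easy dataset warrants; with ~75 optimizer steps per fold
the paper-scale 1e-4 would barely leave initialization. These sizes were
chosen once as the smallest configuration that exercises every component
(all four levels, all three branches, fusion, dense decoder) while training
to held-out Dice ≥ 0.85 in minutes on one CPU.

## Metrics and statistics

Per image: Dice, IoU, recall, precision, specificity from the confusion
counts; HD95 as the maximum of the two directed 95th-percentile
nearest-neighbor distances between 4-connected mask boundaries (linear
interpolation percentile); boundary IoU restricted to the 7×7 ground-truth
band. Degenerate-mask conventions (chosen, the literature is silent):
both masks empty → overlap metrics 1 and HD95 0; exactly one empty →
overlap metrics 0 and HD95 = image diagonal (a bounded sentinel);
predictions binarize at probability 0.5.

Aggregation averages per image within fold, then reports the cross-fold
mean ± SD with a t-distribution 95% interval (df = folds − 1). Paired
comparisons report the paired t test, the Wilcoxon signed-rank test (zeros
dropped; for n ≤ 25 the exact sign-randomization null is computed by a
generating-function convolution over the possibly tied average ranks,
otherwise a tie-corrected normal approximation), paired Cohen's
d = mean(diff)/sd(diff) with the conventional negligible/small/medium/large
labels at 0.2/0.5/0.8, Shapiro–Wilk normality of the differences, and a
caller-supplied Bonferroni multiplier. The Friedman statistic uses the
rank-sum formula `12/(nk(k+1))·ΣR² − 3n(k+1)` over per-image metric
vectors; `stats::friedman.test` serves as an independent cross-check in the
tests. Difficulty stratification splits images by ground-truth-area
terciles and by the 25th percentile of the reference model's per-image
Dice.

## Explainability layer

All attribution methods scalarize the dense output as the **sum of logits
over the predicted foreground** (all pixels if the prediction is empty):
linear, differentiable, and uniform across methods.

* **Grad-CAM++** at any encoder branch/level or decoder node: channel
  weights from the first/second/third gradient powers, ReLU of the
  weighted activation sum, bilinear upsampling, max-normalization.
* **Score-CAM**: channel weight = increase of the target under the input
  masked by the channel's normalized activation, relative to the all-zero
  input; gradient-free by construction.
* **Eigen-CAM**: absolute projection of the pixels×channels activation
  matrix on its first right singular vector, sign-aligned to a nonnegative
  mean.
* **Integrated gradients**: midpoint-rule path integral of the input
  gradient. The default baseline is a strongly blurred copy of the image
  (σ = 8 px) rather than a black image: a constant image collapses the
  normalization statistics, which puts a sharp boundary layer into the
  path integrand and ruins the quadrature, while blurring removes lesion
  structure yet keeps the input in distribution — the same reasoning that
  makes the occlusion baseline a blurred patch. Completeness
  (Σ attributions = target(image) − target(baseline)) is checked
  numerically; on a network this dense in ReLU kinks the midpoint rule
  converges roughly quadratically only asymptotically, so a few hundred
  steps yield percent-level completeness, not machine precision.
* **Kernel SHAP and LIME** over grid-seeded intensity superpixels
  (SLIC-style assignment in (row, col, λ·intensity) space), with occluded
  segments replaced by blurred patches. SHAP solves the
  Shapley-kernel-weighted least squares with the efficiency constraint
  eliminated exactly; when the coalition budget covers all 2^M − 2
  nontrivial coalitions the estimate equals exact Shapley values (the
  tests verify this on additive games). LIME uses an exponential
  proximity kernel and ridge regression. Defaults (50 segments, 1000
  samples) are sized for determinism, not speed; tests use 6 segments
  exhaustively.
* **Attention rollout**: per level, head-averaged attention plus identity,
  row-renormalized; coarser grids are expanded to the finest token grid
  (each coarse token spreads uniformly over its s×s block, preserving row
  stochasticity) and the matrices are multiplied deepest-last; the rows of
  predicted-foreground tokens are averaged into the map.
* **MC-dropout uncertainty**: T = 30 stochastic passes with dropout
  active; per-pixel mean and population SD of the probabilities (population
  rather than sample SD so that the 0.5 bound holds exactly and identical
  passes give exactly zero).
* **Branch contribution**: the learned fusion weights of one auxiliary
  branch are pinned to zero at every level, the remaining weights
  renormalized per sample, and the mean Dice re-evaluated.

Quantitative validation: the normalized energy attribution ratio
(nEAR — attribution energy is the sum of absolute values, so signed maps
are handled; uniform maps score exactly 1), top-k% hit rates with fixed
row-major tie-breaking, pairwise Spearman/SSIM consistency matrices
(SSIM: two-constant form, 7×7 uniform window, both maps normalized to
[0, 1]), the uncertainty-versus-error report (pooled per-pixel Pearson r
and the per-image variant are both reported, because a single correlation
over images cannot be told apart from pixel pooling in summary statistics;
error/correct and boundary/interior mean-uncertainty ratios; Cohen's d
between error and correct pixel populations), quartile case selection by
Dice rank, and mean-uncertainty failure flagging.

## Reproducibility and problem sizes

Every stochastic component (phantoms, initialization, shuffling,
augmentation, dropout, coalition sampling) draws from seeds derived from a
single base seed; identical configuration and seed reproduce histories and
reports byte for byte on a single CPU worker. The test suite runs the full
miniature protocol (160 phantoms, 2 folds, 5 epochs) once and reuses the
trained models across checks; unit tests use 32 px configurations. The
acceptance script (`scripts/acceptance.R`) regenerates the phantom dataset,
reruns the miniature cross-validation from scratch and recomputes the
held-out metrics and XAI statistics it reports.

## Known limitations

* The phantoms are statistical caricatures of B-mode ultrasound; results
  on them bound correctness, not clinical performance.
* Printed parameter counts of the original-scale architecture depend on
  decoder and stem details that are not fully specified anywhere; the
  package asserts only structural orderings between ablation variants.
* The engine is CPU-only and double precision; the paper-scale
  configuration (256 px, channels up to 512) forwards correctly but is not
  practical to train in this implementation.
* Exact Wilcoxon inference is limited to n ≤ 25 per comparison (beyond
  that the tie-corrected normal approximation is used).
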