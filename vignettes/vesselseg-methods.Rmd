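---
title: "Methods: an SE-gated residual recurrent U-Net for retinal vessel segmentation"
author: "vesselseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an SE-gated residual recurrent U-Net for retinal vessel segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselseg)
```

## The problem

Retinal fundus photographs show the vascular tree of the eye: a branching
network of dark curvilinear structures on a brighter, unevenly illuminated
circular field of view (FOV). Segmenting vessels pixel by pixel supports
screening for diabetic retinopathy and other vasculopathies, but manual
delineation is slow and rater-dependent. The task is a heavily imbalanced
binary pixel classification: roughly a tenth of the FOV is vessel, the rest
background, and the clinically interesting structures (small vessels,
branch points) are exactly the ones a naive classifier misses.

`vesselseg` implements a compact convolutional encoder–decoder for this
task together with everything around it: intensity preprocessing, a random
patch training pipeline, Dice-loss training, a pixel-level evaluation suite,
and a synthetic fundus generator so that the whole system is testable
without any external imagery.

## Preprocessing

All learning happens on the green channel, which in fundus photography
carries the strongest vessel/background contrast. The intensity pipeline is

1. **standardise + min–max normalise** — the plane is centred and scaled to
   unit variance, then linearly mapped to $[0,1]$. The composition is a
   monotone map invariant to any affine rescaling of the raw intensities;
   a constant (blank) plane is returned as zeros with a warning rather than
   an error so batch jobs survive border images.
2. **gamma correction** — $V_\mathrm{out} = A\,V_\mathrm{in}^{\gamma}$ with
   $A = 1$ so the unit interval maps onto itself. The exponent is a free
   parameter; the default $\gamma = 1.2$ applies the mild mid-tone
   compression commonly used on fundus images. $\gamma$ and $A$ are exposed
   in every entry point.
3. **CLAHE** — contrast-limited adaptive histogram equalisation
   (via `EBImage::clahe`) with clip limit 2 on an $8\times8$ tile grid,
   both configurable. CLAHE is applied after the gamma step by default;
   a flag reverses the order since the two stages do not commute.

Normalisation statistics are computed over the whole plane by default, with
a flag to restrict them to FOV pixels. An optional pre-enhancement hook can
run an external tool (for example a super-resolution enhancer) on the image
before the pipeline; it is disabled by default and nothing in the package
depends on it.

## Patch pipeline

Training uses small square patches rather than whole images. Collections
are split 1:1 into training and test halves, with a fifth of the training
half flagged for validation (4 of 20 for a DRIVE-sized collection, 2 of 10
for a STARE-sized one), deterministically in a seed. From each training
image a fixed number of patches (default 9,500) is cropped at positions
uniform over the valid top-left corners, with the patch centre constrained
to the FOV when a mask exists. Optional augmentation rotates each
input/label pair by a common random angle — bilinear interpolation for the
input, nearest-neighbour plus a 0.5 threshold for the label so it stays
binary. Full-image prediction covers the plane with a stride grid and
averages all patch predictions overlapping each pixel; extraction followed
by reconstruction on a covering grid is the identity, which the tests
assert exactly.

The default patch size is 48 pixels, matching the published architecture
table whose shapes and parameter counts the tests pin; the alternative
96-pixel setting that appears in the training-parameter table of the same
source is available through the configuration. A "downsampling ratio"
setting printed there has no defined semantics that we could reconstruct;
it is accepted and stored as an inert passthrough.

## The network

The model is a U-shaped fully convolutional network with four encoder
stages of widths 16/32/64/128 (2× max-pooling between stages; a 48×48 input
passes through 48 → 24 → 12 → 6), a width-128 bridge, and a mirrored
decoder whose features are fused with the encoder skips by elementwise
summation. Every stage is built from the same unit:

* **Recurrent convolution.** A single shared 3×3 convolution $K$ (with
  bias) maps the stage input to the stage width. The unit iterates
  $o_k = \mathrm{ReLU}(\mathrm{BN}(K(x) + o_{k-1}))$, $o_0 = 0$, for $t$
  steps — a recurrent convolutional layer whose recurrent kernel is fixed
  to the identity, so the feedback is parameter-free, the batch-norm scale
  and offset are shared across steps, and the parameter count is
  independent of $t$. With $t = 1$ the unit is exactly a plain
  conv + BN + ReLU block. Default $t = 2$, the usual choice for recurrent
  residual U-Nets.
* **Squeeze-and-excitation gate.** Global average pooling gives one scalar
  per channel; a bias-free bottleneck pair of fully connected maps
  ($C \to C/r \to C$, ReLU then sigmoid, reduction $r = 4$) produces
  per-channel gates in $(0,1)$ that multiply the feature map. Zero input
  therefore yields zero output, and channels with identical content under
  tied weights receive identical gates — both covered by tests.
* **Residual skip.** The stage input is added to the gated branch through a
  bias-free 1×1 projection when the widths differ (identity otherwise),
  followed by a final ReLU. The skip keeps gradients alive when the branch
  saturates, which a finite-difference test verifies directly.

Decoder stages upsample with a 2×2 stride-2 **transposed convolution**
(with bias) that also halves the channel count, then add the matching
encoder skip and apply the same unit at the stage width. Nearest-neighbour
upsampling followed by a 1×1 convolution is available as a configuration
alternative. The head is a 1×1 convolution to one channel with a sigmoid.

The `variant` flag degrades the unit for ablations: `unet` (plain blocks),
`recurrent` (recurrence only), `se_resnet` (SE + residual, $t=1$), `r2`
(recurrence + residual), and the full `serr`.

### Parameter accounting

With the conventions above — biased 3×3 stage convolutions, four tracked
per-channel batch-norm quantities (scale, offset, running mean, running
variance), bias-free residual projections, bias-free SE pair at $r = 4$ on
all eight blocks, biased transposed convolutions, biased 1×1 head — the
assembled serr model totals exactly **370,817** parameters:

```{r params}
summary(build_model(network_config()))
```

These conventions were chosen once, as a set, so that the assembled total
matches the published figure exactly while every per-layer number remains
the closed-form count of its layer ($k^2 c_i c_o + c_o$ for a biased
convolution, $4c$ for batch norm: 9,248 for 32→32, 36,928 for 64→64,
147,584 for 128→128). The same accounting is recomputed at run time by
`count_parameters()` and `scripts/acceptance.R`, never stored.

### Numerical choices

* Weight initialisation: variance-scaled Gaussians
  ($\sigma = \sqrt{2/\mathrm{fan_{in}}}$), deterministic in the
  configuration seed.
* Batch normalisation: $\varepsilon = 10^{-5}$; running statistics with
  momentum 0.9. The smaller momentum (rather than the 0.99 used by some
  frameworks) matters at desk scale: after a few hundred optimisation
  steps a 0.99 running average still lags the batch statistics badly, and
  inference-mode predictions are uncalibrated even though training-mode
  accuracy is high.
* Convolutions run as im2col + BLAS matrix products in double precision;
  all backward passes are hand-derived and checked against central finite
  differences in the test suite (worst relative error around $10^{-6}$ on
  the full graph).
* Max-pooling breaks ties toward the first (top-left) maximum;
  binarisation uses the $\ge$ convention at threshold 0.5.

## Training objective

The loss is the smoothed soft Dice loss
$$ L_\mathrm{dice} = 1 - \frac{2\sum_i p_i g_i + s}{\sum_i p_i^2 + \sum_i g_i^2 + s}, \qquad s = 10^{-7}, $$
chosen over cross-entropy because of the 9:1 class imbalance: a classifier
that predicts background everywhere earns almost nothing under Dice. The
smoothing constant makes the empty-vs-empty case a perfect 0 instead of
0/0. The optimised objective adds an L2 penalty,
$L = L_\mathrm{dice} + \lambda\lVert w \rVert_2^2$ with $\lambda = 10^{-4}$
by default, applied to convolution/projection/SE weights (not biases or
batch-norm terms, the usual weight-decay convention).

Optimisation is Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$) at learning rate
0.001 on shuffled mini-batches of 25 patches. A "learning step" of 5 is
interpreted as a decay interval — the rate halves every 5 epochs — and can
be switched off. After each epoch the model is scored on a validation
patch set in inference mode, and the weights with the lowest validation
Dice loss are the ones the fitted object keeps (`final_params` retains the
last-epoch weights). Batch-norm statistics together with L2 regularisation
also act as the overfitting guard: at toy scale the smoothed validation
loss trends downward with $\lambda > 0$, which the suite asserts as a
direction, not a magnitude.

## Evaluation

Scoring is pixel classification against the ground truth, restricted to
FOV pixels when a mask exists (the field's convention; a flag disables
it). From the confusion counts: accuracy, sensitivity (recall),
specificity, precision, F1 ($= TP/(TP + (FP+FN)/2)$, the harmonic mean of
precision and recall), and mean IoU over the two classes with empty-union
classes skipped rather than scored zero. Metrics with zero denominators
are reported as `NA`, never silently as 0. Threshold-free ranking quality
is the ROC/AUC: a sweep over all distinct score values traced from (0,0)
to (1,1), integrated trapezoidally — which equals the probability that a
random vessel pixel outscores a random background pixel, ties counting one
half. The tests hold this identity against an $O(n^2)$ concordance oracle
on randomised instances and against an independent ROC implementation.

## The synthetic generator

Real DRIVE/STARE-scale training is out of desk reach, so the package ships
a generator that emulates the statistical structure the method assumes: a
circular FOV disc on a dark border; a vessel tree grown from an
optic-disc-like origin as recursively branching quadratic Bézier curves
with tapering width, rasterised with Gaussian cross-sections
(max-composited so crossings do not thicken) and thresholded for the exact
mask; vessels darker than background in the green channel; a radial
illumination falloff; additive Gaussian noise. Trees are added until the
vessel fraction approaches the 10% class balance typical of real fundus
images (the default acceptance band is 5–15% of FOV pixels). Everything is
bitwise deterministic in the seed. Difficulty knobs (noise, contrast,
minimum branch width) are exposed; increasing the noise strictly lowers
the AUC of a fixed difference-of-Gaussians matched filter, which the tests
use as a sanity ordering for benchmark difficulty.

What the generator does *not* emulate: pathology (exudates, haemorrhages),
the optic disc and macula as photometric structures, camera vignetting
beyond a radial gradient, JPEG artefacts, or inter-image intensity
statistics of any real dataset. Tests passing on synthetic data therefore
demonstrate that the pipeline, optimiser and evaluator work and that the
architecture can learn dark curvilinear structures under noise — not that
the published accuracy on real datasets is reproduced.

## Problem sizes used by the checks

The test suite trains the full 370,817-parameter model on 2,000 patches of
48×48 (a tenth held out for validation) for 5 epochs at batch 25 under
three seeds, then scores a held-out synthetic image; these sizes exercise
every component at a scale a laptop CPU handles in minutes. Unit tests use
a miniature two-stage network (widths 4/8, 8–16-pixel patches) whose
gradients are cheap enough to check against finite differences
exhaustively.

## Known limitations

* No GPU path and no minibatch parallelism; throughput is a few dozen
  48×48 patches per second per core.
* GIF masks (as shipped with one public dataset) are not readable — no
  installed reader exists; convert masks to PNG first. PPM/PGM, PNG and
  TIFF are supported.
* The published per-layer parameter table contains an internally
  inconsistent row (147,712 for a 3×3 128→128 convolution, which has
  147,584 parameters for any bias convention); the package reports the
  closed-form count and treats the published *total* as the binding
  constraint.
* Training at the published scale (285,000 patches, 20 epochs) is
  supported by the code but takes hours on CPU.
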