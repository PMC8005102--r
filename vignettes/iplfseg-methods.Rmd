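---
title: "Imbalance-aware ultrasound lesion segmentation with iplfseg"
author: "iplfseg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imbalance-aware ultrasound lesion segmentation with iplfseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iplfseg)
```

## The problem

Musculoskeletal ultrasound frames showing a rotator cuff tear (RCT) are a
textbook case of doubly imbalanced segmentation data. At the pixel level the
lesion — a hypoechoic (dark) region inside the tendon strata — typically
covers well under 10% of the frame; at the image level the clinical corpora
are dominated by lesion-positive frames (on the order of 90%). On top of
that, coherent ultrasound imaging carries multiplicative speckle noise that
degrades contrast. Standard per-pixel losses (binary cross-entropy, focal
loss) let the abundant background dominate the gradient signal, and trained
networks under-segment the lesion.

`iplfseg` implements two remedies and the scaffolding needed to study them
end to end on synthetic data:

1. the **integrated-on-positive loss function (IPLF)**, an asymmetric
   per-pixel loss that amplifies gradients on lesion pixels and bounds the
   penalty on background pixels, and
2. a **dual-encoder U-Net-style network** whose second encoder is a frozen
   copy of a classification network pre-trained to detect lesion presence,
   feeding its features into the decoder alongside a task-trained encoder.

## The loss

For ground truth $y \in \{0, 1\}$ and predicted foreground probability
$\hat y$, the loss is

$$
L(y, \hat y) \;=\; y \,\log\!\Big(1 - \big(\alpha + \tfrac{1}{\hat y}\big)^2
\log \hat y\Big) \;-\; (\beta \hat y)^2\,(1 - y)\,\log(1 - \beta \hat y),
$$

with natural logarithms and gradient-weight constants $\alpha$ (positive
branch) and $\beta$ (background branch). Defaults are $\alpha = 0.5$,
$\beta = 0.95$; both are exposed through `lossParams()` because the two
branches are governed independently — the $y=1$ term contains no $\beta$
and the $y=0$ term no $\alpha$ (`gradientSurface()` tabulates this).

Properties that drive its behaviour, all of which are tested:

- for $y = 1$ the loss diverges as $\hat y \to 0$ and its gradient
  magnitude dominates both cross-entropy and focal loss ($\gamma = 2$)
  across the whole unit interval;
- for $y = 0$ the loss is *bounded* by $-\beta^2 \log(1-\beta)$ (about
  2.70 at $\beta = 0.95$) — a confident false positive costs a fixed,
  modest penalty where cross-entropy would diverge;
- predictions are clipped to $[\varepsilon, 1-\varepsilon]$
  ($\varepsilon = 10^{-7}$) so every value and gradient is finite.

```{r curves}
head(tabulateCurves(1, c(0.1, 0.5, 0.9)))
```

The printed term `(α+1ŷ)` of the loss is read as $\alpha + 1/\hat y$: that
reading diverges for confidently wrong positive predictions and vanishes
for correct ones, matching the published value/gradient curves, whereas the
alternative reading $(\alpha + 1)\hat y$ would assign zero loss to a
maximally wrong positive prediction. The focal baseline uses the canonical
$\gamma = 2$ and no class-balancing weight; the F1 baseline is the
soft-Dice complement $1 - 2\sum y\hat y / (\sum y + \sum \hat y)$, the
standard differentiable surrogate for a loss that its originators leave
undefined. Per-batch reduction of the pointwise losses is the arithmetic
mean.

## Evaluation metrics

`confusionCounts()` tallies TP/FP/FN/TN between binary masks;
`segmentationScores()` derives precision, recall, Dice
($2TP/(2TP+FP+FN)$), accuracy, specificity and balanced accuracy.
Degenerate $0/0$ ratios follow a *both-empty convention*: an image without
any lesion for which the model predicts no lesion scores 1 on precision,
recall and Dice (correctly recognising "no lesion" is a correct answer); a
zero denominator with foreground present elsewhere scores 0. Probability
maps are binarised at 0.5, with ties counted as positive.

`fpRatio()` exploits the identity
$FP = \frac{1-P}{P} \cdot R \cdot \text{Positive}$: when two systems are
evaluated against the same ground truth the positive count cancels, so the
ratio of their false-positive counts is computable from the four printed
precision/recall values alone.

## Speckle injection at calibrated PSNR

`addSpeckle()` corrupts an image with multiplicative Gaussian speckle
$x \mapsto x(1 + n)$, $n \sim N(0, \sigma^2)$ — the canonical speckle model
of common imaging toolkits — and calibrates $\sigma$ by bisection until the
PSNR of the returned image hits the requested operating point (15, 12 or
10 dB are the canonical sweep levels) within ±0.1 dB. A numerical choice
worth recording: the bisection measures PSNR on the *clipped* output, so
the guarantee applies to the image actually returned; at 10 dB the [0, 1]
clipping bias is material, and calibrating before clipping would miss the
target by more than the tolerance. The noise field is drawn once per seed,
making outputs bit-reproducible, and zero-intensity pixels stay exactly
zero under the multiplicative model.

## The synthetic phantom generator

Clinical RCT ultrasound data are not publicly deposited, so the package
ships a generator whose *statistical* structure mirrors the study corpus
it emulates — it makes no attempt at anatomical realism:

- 35 patient groups × 40 images (1400 images) by default, split 21/7/7
  patients at a 3:1:1 ratio into 840/280/280 images;
- ~91% of images lesion-positive (1280/1400);
- horizontally layered bands of band-limited speckle texture imitating
  tendon strata, built from two sinusoidal intensity profiles modulated by
  a Gaussian-smoothed noise field (`textureScale` = 1.5 px);
- at most one lesion per image: a darker (hypoechoic) irregular ellipse —
  radius modulated by low-order harmonics — placed in the central band,
  with pixel fraction drawn from [1.5%, 9%] and a hard cap of 10%
  (rejection sampling, 100 attempts); the interior is darkened by
  `intensityContrast` = 0.35, a moderate-contrast regime;
- every sample is deterministic given `(seed, index)`, and the patient id
  is `index %/% imagesPerPatient + 1`.

Augmentation produces six variants per image by default (original plus
five draws composed of horizontal flips, multiplicative intensity jitter
in [0.8, 1.2], and random crops of 70–95% linear size resized back), so an
840-image training partition becomes 5040 images. Three augmentation
types alone cannot produce a ×6 factor, hence compositions. Masks undergo
exactly the geometric transforms with nearest-neighbour interpolation
(keeping them binary); jitter never touches the mask.

What passing tests on these phantoms does and does not show: the phantoms
reproduce the *imbalance* and *noise* structure the loss and architecture
are designed for, but not the low-contrast boundaries, acoustic shadowing
or anatomical variability of clinical ultrasound. Directional conclusions
(loss A beats loss B under imbalance) are meaningful at this scale;
absolute clinical scores are not.

## Architecture and training

Both encoders follow a VGG-style pattern at configurable scale: two 3×3
convolutions per level, each followed by group normalisation (4 groups by
default — the cited group-norm recipe for mini-batches of 8 fixes no group
count) and SeLU activation, then 2×2 max pooling, with one bottleneck
block after the last pool. Channel widths double per level from
`baseWidth`. The classification head applies global average pooling,
dropout 0.75 (pre-training only, never at inference) and a 2-class
softmax. The decoder upsamples (nearest-neighbour), concatenates the skip
features of the selected encoder(s) — channel concatenation is the fusion
rule, the published description fixing only *that* both encoders reach the
decoder — applies a convolution block per level and ends in a 1×1
convolution with a per-pixel 2-class softmax (a 1-channel sigmoid would be
equivalent; the 2-class softmax is the described output). Losses are
evaluated on the foreground-class probability against the binary mask.
Parameters are LeCun-normal initialised, matching the SeLU
self-normalising regime.

Training follows the two-phase protocol:

1. **Pre-training** (`pretrainEncoder()`): the classification encoder is
   optimised on image-level lesion-presence labels — with the IPLF by
   default, since those labels are imbalanced too — and stops at the first
   epoch whose validation accuracy reaches 80%. The stop is part of the
   protocol: classifiers pushed beyond that point have been observed to
   yield worse downstream segmentation, a phenomenon whose mechanism is an
   open question; the package implements only the stopping rule.
   Validation accuracy gates the stop; test accuracy is reported.
2. **Segmentation** (`trainSegmentation()`): the trainable encoder and
   decoder are optimised while the pre-trained encoder is frozen — its
   parameter digest is byte-identical before and after, which is asserted
   in the tests. Because the frozen encoder never changes, its features
   per training image are computed once and cached for all epochs, which
   is numerically identical to recomputing them.

Optimisation uses Adam with moment decays 0.99/0.999, mini-batches of 8,
and a learning rate starting at 0.001 halved every 40 epochs. Runs are
bit-reproducible given a seed under single-threaded execution;
multi-threaded BLAS is permitted but exempt from bit-level reproducibility.
Patient-level 5-fold cross-validation (`crossval()`) rotates 3:1:1 roles
over patient folds, never splitting a patient across partitions.

## Desk-scale benchmarks

The full-scale protocol (1400 images, 250 epochs, 5 folds, GPU-scale
networks) is configuration, not test surface. The shipped benchmark
(`runBenchmark()`) uses deliberately small problem sizes chosen as the
package's own desk-scale defaults: 300 images (15 patients × 20) at 64×64,
a `baseWidth` 4 / 3-level network, 30 segmentation epochs, a 10-epoch
pre-training budget, and three seeds. At these sizes the corpus positive
pixel fraction is ≈5%. The benchmark trains the plain U-Net under BCE and
IPLF, the dual-encoder model under IPLF, and sweeps the trained models
over 15/12/10 dB speckle. The interesting quantities are directional:
whether IPLF beats BCE at equal architecture, and whether the dual-encoder
model holds up better as noise grows.

Two caveats the benchmark itself exposes. First, the phantom lesions are
higher-contrast than clinical RCTs, so BCE remains competitive on Dice at
this scale even while the IPLF reproduces its characteristic
recall-over-precision trade; the regime where cross-entropy collapses
(precision near 0.2 on clinical corpora) is not reached on easy synthetic
data. Second, models trained on clean phantoms are brittle to test-time
speckle in a way clinically trained models — which see inherently speckled
images throughout training — are not: below 15 dB their Dice drops to a
noise floor where comparisons between models measure floor fluctuation
rather than robustness. Both behaviours are faithfully reported by the
acceptance checks rather than smoothed over.

A related protocol consequence: with ~91% lesion-positive images, the
80%-accuracy pre-training stop triggers after a single epoch (the
majority-class classifier already exceeds the threshold), so the frozen
encoder contributes weakly trained features. The stopping rule is part of
the protocol and is implemented as stated; configurations with a higher
`pretrainTargetAccuracy` train the classifier further.

## Numerical choices and limitations

- Compiled 3×3 convolution kernels run single-precision GEMM (the usual
  deep-learning arithmetic) behind an im2col layout shared by the whole
  mini-batch; pooling, upsampling, group norm, SeLU and all reductions are
  double precision. A pure-double reference convolution
  (`options(iplfseg.referenceConv = TRUE)`) exists for verification; the
  analytic backward pass agrees with central finite differences to ~1e-9
  relative error on that path.
- Group-norm variance uses an epsilon of 1e-5; Adam uses 1e-8.
- Binarisation ties (probability exactly 0.5) count as positive.
- Mask resizing uses nearest-neighbour interpolation so masks stay binary.
- The speckle generator is the generic multiplicative Gaussian model, not
  a physical Rayleigh/K-distribution scatterer simulation.
- The phantom generator draws lesion-presence per image independently, so
  realised label counts fluctuate binomially around the configured
  fraction.
- Boundary/surface-distance metrics (e.g. Hausdorff) are out of scope; the
  evaluation protocol is confusion-count based.
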