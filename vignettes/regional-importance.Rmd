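---
title: "Regional importance mapping with CAMs and adversarial perturbation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional importance mapping with CAMs and adversarial perturbation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Class activation maps (CAMs) are routinely used to visualize which parts of a
medical image a convolutional classifier attends to, but a heat map on its own
is only a picture: it does not establish that the highlighted sub-regions
actually *matter* for the prediction. For ultrasound nodule diagnosis this
question has clinical weight — if the hot regions of a malignancy heat map
carry the diagnostic signal, they are natural targets for fine-needle
aspiration biopsy sampling.

`camsens` implements a quantitative protocol for that question:

1. compute the CAM of a global-average-pooling (GAP) classifier and its
   malignancy-probability-scaled variant;
2. partition the nodular CAM into five equal-area nested level-set regions,
   from the coolest rim (region I) to the hottest core (region V);
3. perturb each region — and only that region — with single-step FGSM
   adversarial noise, randomizing the perturbed positions five times;
4. measure the damage to the dataset-level AUC per region and compare regions
   with DeLong's paired test and with paired t-tests over random subsets.

Regions whose perturbation hurts the AUC most are the regions the classifier
relies on most.

## The model quantities

For an input image, let $g_k(x, y)$ be the activation of feature map $k$ of
the last convolutional layer. Global average pooling is implemented as the
spatial sum $G^k = \sum_{x,y} g_k(x,y)$, the head is a single linear map with
weights $\omega_k^i$ and **no bias**, the class score is
$S_i = \sum_k \omega_k^i G^k$, and $P_i = \exp(S_i)/\sum_j \exp(S_j)$. The
class activation map is

$$M_i(x, y) = \sum_k \omega_k^i \, g_k(x, y),$$

which satisfies the exact identity $S_i = \sum_{x,y} M_i(x,y)$ — enforced in
the test suite at $10^{-5}$ on random batches. (Had pooling been implemented
as a spatial *mean*, the head weights would need rescaling by the grid size
for the identity to hold; the sum convention avoids the factor.)

The **malignancy heat map** rescales the clamped malignant-class CAM by its
per-nodule maximum and multiplies by $P_\text{malignant}$, so peak heat
equals the predicted malignancy probability and color temperature encodes
absolute, not relative, evidence. Negative CAM values (possible because
$\omega$ can be negative) are clamped to zero for rendering and
segmentation; the raw signed map is retained for the sum-to-score identity.

FGSM noise is $\delta = \beta\,\mathrm{sign}(\nabla_x L(x, y, \phi))$ with
$\mathrm{sign}(0) = 0$, where $L$ is the cross-entropy on the true label and
$\beta$ bounds the max-norm of the pixel change. Perturbed images are clipped
to $[0, 1]$.

## The synthetic phantom: what it emulates and what it does not

The clinical datasets this protocol was designed for are not publicly
available, so the package ships a seeded B-mode phantom
(`phantom_config()`, `generate_dataset()`) that serves as the test
substrate. Each image is an elliptical nodule in a uniform parenchyma,
multiplied by a unit-mean gamma speckle field (`speckle_scale = 0.35`,
roughly the granularity of coarse B-mode texture) and clipped to $[0,1]$.
The class signal is deliberately *localized* so that regional-importance
claims have a ground truth:

* malignant nodules carry a very hypoechoic cue region (envelope at 35% of
  the nodule level) covering about a quarter of the nodule at the configured
  localization (`center` by default), plus 2–5 punctate bright foci and a
  sinusoidally irregular margin (amplitude 0.15);
* benign nodules are smooth ellipses at a brighter echogenicity.

Class mean echogenicities (benign 0.52, malignant 0.42 against a 0.45
background) sit close together, and each nodule draws its own level with SD
0.08, so overall brightness alone does not separate the classes — some benign
nodules are darker than some malignant envelopes. This choice keeps the
stand-in classifier honest (probabilities do not all saturate, the >0.4
malignancy cohort retains benign members) while a simple pixel-statistics
classifier still reaches AUC > 0.9, guaranteeing learnable signal. A
128-pixel image keeps CPU training in the minutes range.

What the phantom does **not** emulate: acoustic wave propagation, depth
attenuation, anisotropic point-spread functions, shadowing behind
calcifications, 3-D structure, or the anatomical diversity of real glands. A
green test on the phantom therefore establishes that the *machinery* —
CAM arithmetic, partitioning, perturbation, statistics — behaves as
specified and that regional importance is recoverable when it exists by
construction; it does not certify performance on clinical images.

## The stand-in classifier

No deep-learning framework is assumed: `gapnet` is a three-block CNN
(8/16/32 feature maps, stride-2 convolutions down to a 16×16 grid, ~6k
parameters) with GAP-sum pooling and a bias-free linear head, implemented in
plain R with im2col/BLAS convolutions and manual backpropagation. This keeps
every quantity the protocol consumes — $g_k$, $\omega$, $S_i$, and exact
input gradients — directly inspectable, and the input gradient is verified
against central finite differences in the tests. Training is Adam on
cross-entropy with a stratified train/validation split, deterministic under
a seed.

## Numerical and design choices

* **Equal-area partitioning** peels the lowest-valued $\lfloor N/k \rfloor$
  support pixels as region I, the next block as region II, and so on — the
  value-quantile construction. Ties (frequent after bilinear upsampling) are
  broken by raster scan order, deterministically. The remainder $N \bmod k$
  goes one pixel each to the innermost regions, so the hot core is never the
  smallest region. Segmentation operates on the upsampled, clamped CAM at
  image resolution, restricted to the nodule mask, so region masks align
  with the image for pixel-level perturbation; if clamping leaves fewer than
  $k$ positive pixels (a map negative over the nodule), a rank-preserving
  shift inside the mask keeps the partition defined.
* **Upsampling** is bilinear with half-pixel center alignment; it is exactly
  the identity when sizes match and never exceeds the source range.
* **"Randomized positions"**: each of the 5 repetitions perturbs a fresh
  uniformly random subset of 80% (`position_fraction`) of the region's
  pixels; applying noise to every pixel would make the repetitions
  identical and their average meaningless. Per-nodule, per-repetition seeds
  derive deterministically from the experiment seed.
* **Noise magnitude** is chosen by the AUC-gradient rule
  (`select_beta()`): whole-nodule FGSM at each grid magnitude, finite
  differences of AUC against $\beta$ (central in the interior, one-sided at
  the ends), and the selectable grid point with the largest $|dAUC/d\beta|$
  wins. The zero grid point is the clean control and is not selectable: a
  null magnitude is not a perturbation size, and for an undefended
  classifier — whose AUC decays fastest immediately at the origin — the raw
  argmax would degenerate to "no noise". The default grid
  `c(0, 0.002, 0.005, 0.01, 0.02, 0.04)` spans the measured decay of the
  stand-in from mild to destroyed.
* **Gradients** are computed once on the clean image with the true label
  (single-step FGSM, no iteration).
* **Cohort rule**: the malignancy-heat-map experiment keeps nodules with
  clean predicted malignancy probability above 0.4. Because the
  malignancy heat map is a positive rescaling of the clamped malignant-class
  CAM, its equal-area partition coincides with the CAM's own; the variant
  differs through the cohort restriction and the map used for rendering.
* **Subset stage**: `partition_dataset()` implements the documented plain
  random split (blocks of $\lfloor n/k \rfloor$, remainder appended to the
  final subset — sizes 520/520/520/520/522 at $n = 2602$). Inside the
  experiments, however, the >0.4 cohort of a 400-nodule phantom holds only
  a handful of benign nodules and a plain random split regularly produces
  single-class subsets with undefined AUC, so the engine stratifies its
  subsets by class. Subsets that still end up single-class yield `NA` rows
  that are dropped from the paired t-tests with a warning.
* **Degenerate statistics**: DeLong's test returns $p = 1$ with a
  degeneracy flag when the variance of the AUC difference is zero (identical
  scores, or perfect separation in both arms — common on easy phantoms);
  paired t-tests do the same for all-zero difference columns. Rendered
  p-value matrices floor at $10^{-14}$ for display; raw values are kept.
* **Threshold sweep**: the alternative to perturbation keeps nodular pixels
  whose CAM reaches a fraction of the per-nodule maximum and replaces the
  sub-threshold nodular remainder with the image's own parenchyma median —
  blacking out the background instead would push every image far outside the
  training distribution and saturate the classifier into uninformative,
  identical scores (observed during development). AUC declines as the
  threshold rises and nodular evidence is progressively erased.

## What the experiments show on the phantom

`run_experiment_regions()` / `run_experiment_malignancy()` train the
stand-in, calibrate $\beta$, perturb each region with five randomized
repetitions, average the malignancy probabilities, and emit per-region
ROC/AUC, the DeLong p-value matrix, and the subset-level paired t-tests.
With centrally localized cues, region V (the hot core) overlaps the cue in
~90% of its pixels and the model's input-gradient magnitude rises
monotonically from region I to region V, so perturbing the core damages the
cohort AUC more than perturbing the rim — the acceptance suite checks this
directionally over three seeds, alongside a held-out clean AUC of at least
0.90. The numbers printed by the original clinical study (dataset AUC
0.9302, median Dice > 0.9) are properties of a restricted dataset and a
commercial model and are *not* reproduction targets; the phantom
experiments test the protocol, not those values.

## Known limitations

* The stand-in classifier is intentionally small and adversarially fragile;
  the calibrated $\beta$ is therefore much smaller than what a robust
  clinical model would need, and per-region AUC differences are
  correspondingly fine-grained.
* The phantom's cue geometry makes "core matters most" true by
  construction when `cue_localization = "center"`; the annulus and random
  modes exist precisely to vary that ground truth.
* Dice evaluation compares CAM-derived masks against ground-truth phantom
  masks; it is a smoke check of localization plumbing, not a segmentation
  benchmark.
* Only the scoring arithmetic of ACR TI-RADS is implemented (echogenicity,
  composition, echogenic foci — the attributes that can be rated on
  sub-nodular components); whole-nodule shape and margin attributes and the
  TR1–TR5 level assignment are out of scope. Non-solid compositions never
  occur in the bundled reader-study table and are rejected by validation
  rather than silently mis-scored; extending `risk_point_map()` with the
  cystic/spongiform/mixed point values is the documented path if such
  ratings appear.
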