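---
title: "Adversarial deformable MR–ultrasound registration: models, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial deformable MR–ultrasound registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

During image-guided neurosurgery the brain deforms after the craniotomy
("brain shift"), so the pre-operative MR scan no longer aligns with the
patient.  Intraoperative ultrasound (iUS) images the current anatomy but is
noisy, speckled and has a restricted field of view.  Updating the
navigation therefore requires deformable *multimodal* registration: warp
the pre-operative MR slice onto the iUS grid so that corresponding anatomy
coincides.  Accuracy is measured on expert landmark pairs by the mean
target registration error,

$$\mathrm{mTRE} = \frac{1}{N}\sum_{i=1}^{N}\lVert T(x'_i) - x_i\rVert,$$

the average distance in mm between the fixed-image landmarks mapped through
the recovered transform $T$ and their counterparts in the moving image.

## The model

`ganreg()` trains, without any ground-truth alignment, one generator and
two discriminators:

* **Generator** — a convolutional autoencoder (five stride-2, 3×3 encoder
  stages and five stride-2 up-sampling decoder stages, batch norm +
  rectifier) that reads the stacked (iUS, MR) pair.  In the default
  *field* mode its 2-channel output is squashed by
  $u = u_{\max}\tanh(\cdot)$ and interpreted as a dense displacement field
  in mm on the fixed grid, pull-back convention: the registered image is
  $\mathrm{MR}(x + u(x))$ by differentiable bilinear resampling.  The
  output stage is zero-initialized so training starts at the identity
  transform.  An *image* mode that emits the registered image directly is
  also provided; it mirrors the architecture literally but yields no
  transform, so landmark error cannot be evaluated in that mode.
* **Discriminators** — D1 judges candidates against real ultrasound, D2
  against real MR (stride-2 conv stacks with a dense tanh head mapped
  affinely onto (0, 1) and clamped, because the objectives take
  $\log D$ and $\log(1-D)$).  By default each sees a single channel,
  matching the adversarial objectives exactly; a `conditional` switch
  concatenates the other-modality source as a second channel.

The objectives, per batch:

* adversarial: $L_G = \mathbb{E}\log(1-D_1(G)) + \mathbb{E}\log(1-D_2(G))$
  (saturating form; a non-saturating option exists), and
  $L_{D_k} = \mathbb{E}[-\log D_k(\text{real})] +
  \mathbb{E}[-\log(1-D_k(G))]$;
* mutual information: $L_{MI,D_1} = 1 - \mathrm{NMI}(G, \mathrm{iUS})$ and
  $L_{MI,D_2} = 1 - \mathrm{NMI}(G, \mathrm{MR})$ with
  $\mathrm{NMI} = 2I/(H_1+H_2) \in [0,1]$, estimated on a B×B joint
  intensity histogram;
* Bayesian: $L_B = 1 - \frac{1}{N}\sum_x q\!\left(b_G(x) \mid
  b_{MR}(x), b_{US}(x)\right)$, the mean posterior probability of the
  registered image's intensity bin given the source bins, from a triple
  histogram — 0 exactly when the registered intensity is a deterministic
  per-bin function of the sources, $1 - 1/B$ under independence.

Totals are composed as $L_G + \lambda_B L_B$ for the generator and
$L_{D_k} + \lambda_{MI} L_{MI,D_k}$ for the discriminators.  The printed
min/max operators of the source formulations are read as normalization
devices: both similarity terms are implemented as "1 − (bounded dependence
measure)" so every loss lives in [0, 1] and is testable.

### Differentiable histograms

Hard binning is the oracle-checkable reference (tested against brute-force
enumeration).  For gradient flow the soft mode assigns each pixel Gaussian
kernel weights on the bin centres (width = one bin width by default),
normalized per pixel so each pixel contributes unit mass; losses built on
it have analytic gradients with respect to the images, verified against
numerical derivatives in the test suite, and the bilinear warp likewise
backpropagates into both the field and the moving image.

## Training schedule

The defaults reproduce the published full-scale schedule: 200 epochs,
batch 24, Adam (β = 0.5, 0.999) at learning rate $10^{-5}$ multiplied by
0.85 after every epoch.  Per batch the update order is D1, D2 (real = iUS
resp. MR, fake = the current registered output, detached), then the
generator.  The optimizer, update order and Adam betas are this package's
choices (standard for adversarial training) — the source schedule fixes
only the epoch count, rate, decay and batch size.  Runs are bit-reproducible
from the seed; checkpoints store all weights, batch-norm statistics,
optimizer state and the control object.

Two structural observations about the loss composition, discovered during
development and reflected in the `mi_to_generator` control flag:

1. The MI terms depend only on images, not on discriminator parameters, so
   inside the discriminator objectives they are reported regularizers with
   zero parameter gradient.  The flag routes their image gradient to the
   generator instead.
2. Only the ultrasound-side MI term can drive alignment.  The MR-side term
   compares the warped MR with its own source and the Bayes posterior of a
   warped MR given its source is already maximal at the identity warp, so
   both act as content-preservation anchors; the single-channel
   discriminators cannot sense alignment at all.  With the flag on, only
   the ultrasound-side gradient is therefore routed (all terms are still
   computed, logged and added to the totals).

## The synthetic data generator

`synth_config()` / `generate_case()` emulate the statistical regime the
losses rely on, not ultrasound physics: a cartoon anatomy (cortex ellipse,
2–5 internal structures, one tumour disk) rendered twice — MR-like
(per-class means, smooth multiplicative bias, additive Gaussian noise) and
US-like (class-dependent echogenicity plus label-gradient edge emphasis,
mean-one gamma speckle with variance 1/looks, exponential depth
attenuation, fan-shaped field of view with exact zeros outside).  The
defaults (64×64 px at 1 mm, elastic amplitude 3 mm with 8 mm correlation
length, 10 landmarks, 12-look speckle, 2% MR noise) model moderate brain
shift at desk scale.  Misalignment is constructed by warping the aligned MR
through the approximate inverse of a sampled smooth field, so the emitted
pull-back field re-aligns the pair; landmark pairs are exact by
construction (moving = fixed + u(fixed), < 0.01 mm).  Same-anatomy MR/US
pairs are strongly dependent in NMI while mismatched pairs are not — the
property the similarity losses exploit — but the simulator has no
resection cavities, no 3D geometry, no acoustic shadowing, and its
intensity classes are cleaner than real tissue, so passing tests
demonstrate correctness of the machinery, not clinical performance.

## The desk-scale recovery experiment

Reproducing the published cohort errors requires the real datasets and
long GPU training, which is out of scope.  The package's surrogate,
`translation_recovery()`, freezes this protocol: 20 synthetic cases
misaligned by pure translations of 1–4 px in random directions, field
mode, 200 generator updates in batches of 10, Adam at $1.5\times10^{-3}$
decaying 0.98/epoch, $u_{\max} = 5$ mm, a 12-px smooth field
parameterization (below), $\lambda_B = 1$, `mi_to_generator = TRUE` with
$\lambda_{MI} = 500$, relatively clean ultrasound (32-look speckle, 1% MR
noise); seeds 0–3; success = registered cohort mTRE below half the
initial mTRE on at least 3 of 4 seeds.  The optimizer settings were
calibrated once on this fixture and then frozen.  Three measurements drove
them:

* the published rate ($10^{-5}$ over ~2000 full-scale steps) moves the
  zero-initialized field head far too little in 200 desk-scale steps;
* the adversarial image gradient is roughly two orders of magnitude larger
  than the MI gradient (RMS 0.024 vs 0.0003 on the fixture), so without a
  large $\lambda_{MI}$ the alignment signal is drowned in adversarial
  texture noise;
* the NMI objective itself was verified, before any training, to have its
  minimum at the true shift with a smooth basin wider than the largest
  misalignment — so failures of early protocol drafts were optimization
  artifacts, not a missing signal.

The **smooth field parameterization** deserves its own note.  The raw
per-pixel MI gradient is locally inconsistent (speckle, flat regions), and
with no constraint on the transform the learned fields were spatially wild
(per-component sd ≈ 2 mm against ≈ 1.5 mm true constant shifts), which
*increased* the landmark error even when the field's mean was right.
Unsupervised registration networks conventionally counter this with either
a smoothness penalty on $u$ or a smooth transform model (B-spline
free-form deformations).  The source objectives contain no regularization
energy and this package adds none; instead the field head can include a
fixed, edge-normalized Gaussian smoothing stage
(`field_smooth`, in pixels) before the $\tanh$ bound — a smooth
*parameterization* of the transform, linear and self-adjoint, off by
default and enabled (σ = 12 px) in the recovery protocol where the true
transforms are global translations.

## Numerical choices and degenerate inputs

* Intensities are normalized to [0, 1] at load time (percentile clipping,
  affine map); the histogram losses require a bounded common range.
  Constant images have zero entropy: `mi_loss` returns 1 with a
  degeneracy flag.
* Log arguments are clamped at $10^{-6}$; discriminator outputs are
  clamped to $[10^{-6}, 1-10^{-6}]$.
* Soft-bin rows whose kernel mass underflows (very narrow kernels) fall
  back to a one-hot at the nearest centre — the exact zero-width limit.
* Out-of-domain warp samples are 0 (the dark US background); landmarks
  outside a field's extent are clamped to the border and counted in a
  `clamped` attribute.
* Empty (MR, US) histogram cells cannot hold pixels, so they are excluded
  from the Bayes posterior average by construction.
* The batch-norm variance uses the biased (1/M) estimator with
  $\epsilon = 10^{-5}$; evaluation mode uses running statistics
  (momentum 0.1).
* The signed-rank test drops zero differences; an all-tie comparison
  returns p = 1 with a flag.  The exact null distribution is used for
  n ≤ 25 without ties.

## Evaluation conventions

`mtre()` maps fixed landmarks through the field ($x' \mapsto x' + u(x')$,
bilinear field sampling) and averages Euclidean distances to the moving
landmarks; with no field it reports the pre-registration error.  All TREs
here are 2D (slices).  Cohort summaries use the sample (n−1) standard
deviation — the convention that reproduces the published reference-cohort
summary rows shipped in `resect_mtre_table()` / `bite_mtre_table()` — and
the paired comparison is a two-sided Wilcoxon signed-rank test (the
nonparametric choice for non-normal error differences; the test behind the
published p-values is unnamed, so p-values are reported but never treated
as reproduction targets).  One published summary row (the 22-case
adversarial-only column's standard deviation) is not reproducible from its
own per-case values; the package reports what the per-case values give.

## Problem sizes used by the checks

The test-suite and acceptance computations run on one CPU: loss oracles on
≤ 16×16 images, gradient checks on 8×8, training determinism on 8 pairs of
64×64 for 2 epochs, the recovery experiment as frozen above, and dataset
IO on 32×32 cases.  These sizes are the package's reference conditions;
`ganreg_control()` scales to larger slices (any multiple of 32) unchanged.

## Known limitations

* 2D slices only; the source volumes are sliced and resampled, never
  registered volumetrically.
* No field regularization (smoothness/diffeomorphism penalties) — the
  architecture's receptive field and the tanh bound are the only implicit
  regularizers, exactly as in the source formulation.
* Image mode cannot produce landmark errors (no transform exists).
* The adversarial pathway alone does not align; without the MI gradient
  flag the generator only learns to keep its output realistic.
* Desk-scale training recovers translations; recovering the full elastic
  deformations of real surgical data is expected to require the published
  full-scale schedule and datasets.
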