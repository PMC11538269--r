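---
title: "Multi-modal contrastive pre-training for paired retinal imaging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal contrastive pre-training for paired retinal imaging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A patient's eye is typically imaged with two complementary modalities: a 2D
en-face fundus photograph or near-infrared reflectance image, and a 3D
optical coherence tomography (OCT) volume built from cross-sectional
B-scans. Labels (visual function, biomarkers, prognosis) are scarce, but
*paired* scans of the same eye at the same visit are abundant. retinapair
implements contrastive pre-training that exploits this pairing: a 2D encoder
$h^x$ and a 3D encoder $h^y$ are trained so that embeddings of the fundus
image and the OCT volume of the same eye are close in a shared
$d$-dimensional space while non-matching pairs are far apart. The
pre-trained encoders are then reused for cross-modal retrieval, downstream
prediction by linear probing or fine-tuning, and modality interchange
(feeding fundus embeddings to a head trained on OCT embeddings).

## Objectives

Two multi-modal objectives are provided, operating on row-l2-normalized
embedding batches $U, V \in \mathbb{R}^{n\times d}$ with similarity
$S_{ij} = u_i \cdot v_j$:

* **InfoNCE (CLIP)** — the symmetric mean of row- and column-wise
  cross-entropies of $\mathrm{softmax}(S/\tau)$ against the diagonal. The
  denominator includes the positive pair, so the loss is bounded below by 0
  and approaches $\log n$ for uninformative embeddings.
* **InfoLOOB with modern Hopfield retrieval (CLOOB)** — each batch is first
  passed through a continuous Hopfield memory,
  $H_M(q) = \mathrm{normalize}\!\left(M^\top \mathrm{softmax}(\beta M q)\right)$,
  anchored once in each modality's memory, and the leave-one-out bound
  $-s_{ii}/\tau + \log \sum_{j \ne i} e^{s_{ij}/\tau}$ is averaged over both
  directions. Excluding the positive from the denominator removes the
  saturation floor (the loss can go below zero), and the Hopfield step
  propagates within-modality covariance structure into the objective.

Uni-modal baselines (SimCLR's NT-Xent, BYOL's EMA-target cosine regression,
VICReg's invariance + variance-hinge + covariance penalty) train a single
encoder on two augmented views through a 128-d projection head that is
discarded afterwards. All five losses are written against a small
reverse-mode autodiff layer over dense matrices, so the same loss code
evaluates numerically in tests and differentiates during training; every
loss is checked against a brute-force oracle and finite-difference
gradients.

The temperature is a learnable log-inverse-temperature initialized at
$\log(1/0.07)$ with the inverse temperature clamped at 100 (the OpenCLIP
convention). The fixed-temperature CLOOB variant is available via
`learnable_tau = FALSE`; at desk scale it converged more slowly, so the
learnable default is kept.

## Training protocol

Pre-training uses AdamW (decoupled weight decay 0.1), one randomly selected
(fundus, OCT) pair per patient per epoch, and final-epoch checkpointing.
Per-epoch pair sampling is seeded from the master seed rather than wall
time: reproducibility is worth more here than fidelity to the original
time-based seeding. The learning-rate schedule is a linear warmup (3
epochs) into cosine decay; a constant schedule is available. `select_lr()`
implements the learning-rate search as a small validation-loss grid over
{1e-5, 1e-4, 1e-3}, inside the published search interval [1e-6, 1e-3].

**Hopfield beta.** `cloob_loss()` defaults to $\beta = 8$, the convention of
its source. For *training at desk scale* the default is $\beta = 20$
(`pretrain_config()$hopfield_beta`): with minibatches of 8 the retrieval
softmax at $\beta = 8$ blends the few stored patterns so strongly that pair
identity is lost, and measured test retrieval dropped from ~0.9 to ~0.3
top-1. Sharper retrieval restores the InfoLOOB signal while keeping the
covariance-enriching effect.

## Preprocessing

Both modalities are converted to grayscale (ITU-R 601 weights for RGB),
resized bilinearly, and normalized image/volume-wise to mean 0, sd 1.
Volumes keep `n_keep_slices` B-scans (default 20) by ordered uniform
subsampling, `floor(linspace(0, n-1, k) + 0.5) + 1`, which always includes
the first and last slice and preserves order; with fewer slices than
requested, indices repeat. Resizing uses the align-corners pixel-center
mapping so identity resizes are exact; it is implemented in-package (~30
lines) because the exact convention is part of the tested contract and is
verified against a brute-force per-pixel oracle. Shipping default target
size is 224 x 224.

Augmentations for uni-modal view pairs are center crop (scale drawn from
0.8-1.0, resized back — a conservative reading of "centered crop"),
horizontal flip (both p = 0.5), Gaussian blur (sigma 0.1-2.0) and contrast
adjustment (factor 0.6-1.4, both p = 0.3); blur/contrast ranges follow the
SimCLR convention. A volume is augmented slice-coherently — one parameter
draw applied to every B-scan — so 3D structure is not scrambled.
Multi-modal pre-training uses no augmentation: the natural variation
between repeat visits of the same eye plays that role, which mirrors how
the original pipeline only prescribes view augmentations for the uni-modal
baselines.

## Partitioning

Splits are patient-level (all scans of a patient land in one subset),
80/15/5 for pre-training and 80/10/10 for downstream tasks, with optional
stratification implemented as per-stratum shuffling plus largest-remainder
allocation; realized per-stratum proportions are within one patient of the
targets. Strata smaller than 3 patients go entirely to train with a
warning.

## Downstream adaptation

A single affine head is trained on frozen embeddings (linear probing) or
jointly with the encoder (fine-tuning; an encoder learning-rate scale of 0
reproduces the probe exactly, which is asserted in tests). The task losses
are MSE, binary cross-entropy and cross-entropy; optimization is AdamW with
reduce-on-plateau (factor 0.5, patience 2), at most 100 epochs, and early
stopping after 5 non-improving validation epochs. Three practical choices
make this protocol attainable with learning rates capped at 1e-3: features
are standardized (statistics frozen from the initial encoder's training
embeddings, batch-norm-in-eval-mode style), regression targets are
standardized and back-transformed at prediction, and the head bias starts
at the training base rate. `linear_probe()` accepts any embedding matrix;
the demo probes l2-normalized embeddings, because under cosine-aligned
contrastive training the row norm is an unconstrained nuisance dimension —
measured on the demo cohorts, normalization never hurt the probe and
lifted it substantially on weaker seeds (0.34 to 0.44 at one seed, equal
at another).

Metrics are $R^2 = 1 - SS_{res}/SS_{tot}$ (negative values meaning worse
than the mean predictor) and RMSE for regression, and class-support-weighted
one-vs-rest AUROC and average precision for classification. AUROC is
computed through pROC with a fixed direction (no auto-flip); average
precision is the threshold-stepped estimator. Test metrics are accompanied
by a seeded bootstrap (default B = 1000, resampling at scan level) mean and
SD. Retrieval accuracies carry exact Clopper-Pearson 95% intervals (the
interval method is a package choice; none is named in the original
report).

The interchange evaluation feeds the paired fundus embeddings of the test
set into the head trained on OCT embeddings and reports the relative decay
(source − swapped)/source of the primary metric.

## The synthetic cohort generator

No real scans ship with the package; all rendering choices are stand-ins
whose only purpose is to give the pipeline the statistical structure the
method needs, and they are documented as such. Each (patient, eye) draws an
8-dimensional latent vector $z \sim \mathcal N(0, I)$; repeat visits add
$\mathcal N(0, 0.1^2 I)$ drift so same-eye visits stay closer in latent
space than other eyes. Both modalities render from the same $z$:

* **Fundus** (64 x 64 default): a smooth radial background plus one
  Gaussian blob per latent component on a circle; blob $k$'s amplitude is
  $0.7 + 0.35 z_k$ (floored at 0) and its radial position shifts mildly
  ($3\%$ per unit $z_k$).
* **OCT** (21-256 B-scans of 64 x 64 by default): four bright horizontal
  bands per B-scan. The central band has constant amplitude and thickness
  $\mathrm{clip}(\mathrm{round}(0.18R + 0.045R\,z_1))$ voxels — by
  construction equal to the CST-analog label `y_cst` and measurable on the
  rendered volume by thresholded counting. The three thin bands sit at
  fixed depths and their amplitudes are modulated across slices by
  low-frequency cosines of the remaining components, so noiseless voxel
  intensities are linear in $z$ (up to thickness quantization). A fluid
  event carves a dark ellipsoid into the central slices, off the
  measurement column.

Labels: the visual-acuity analog is linear in $z$ plus measurement noise
(sd 1.5, about a line of letters); fluid presence is Bernoulli with logit
$1.8 z_2$; the disease class is the argmax of five fixed linear logits; the
injection count is Poisson with log-mean $1.9 + 0.45 z_1$ clipped to
[0, 30], categorized as high treatment need at $\ge 16$ injections and low
at $\le 5$; conversion is Bernoulli with logit $-1 + 0.9 z_5 + 0.6 z_6$.
Vendors contribute fixed additive intensity offsets assigned round-robin.

**Noise.** Additive Gaussian noise (sd 0.6 by default, clamped at zero)
dominates the per-voxel lesion contrast (blob amplitude sd 0.35), as in
speckle-dominated clinical scans. This is the property that separates
trained from untrained encoders: recovering the latents requires spatially
integrating matched filters, which contrastive training learns, while a
random-initialization encoder — effectively a random low-dimensional
projection — retains almost none of the latent signal (probing it yields
$R^2 \approx 0$). At the same time, the noiseless renders support an
ordinary-least-squares readout of every latent component from either
modality with $R^2 > 0.9$, which is verified in tests.

What the generator does *not* emulate: anatomy, scanner physics,
vendor-specific texture, longitudinal disease progression, or the
inter-eye correlation of real patients. Passing tests therefore show that
the algorithms behave as specified on data with the right dependence
structure — not that the pipeline reaches any particular performance on
real scans.

## Desk-scale demonstration sizes

`demo_config()` fixes the scales used by `run_demo()` and the end-to-end
tests: 250 patients with 2-4 visits each, 64 x 64 native grids with 21-40
B-scans, preprocessing to 64 x 64 with 10 retained slices, tiny two-layer
dense encoders with $d = 32$ and hidden width 64, minibatches of 6, and 30
pre-training epochs per objective. The demo partitions patients 80/5/15
rather than the 80/15/5 shipping default: training still sees exactly 200
pairs per epoch (one per training patient), but the hold-out retrieval
pool then contains 37 patients instead of 12, large enough that a top-1
accuracy is statistically meaningful. For the same reason the
one-sample-per-patient retrieval accuracy is reported both for a single
visit draw and averaged over 20 seeded draws, and the
random-initialization probe control is averaged over three encoder seeds.
The full run (cohort synthesis, CLIP and CLOOB pre-training, retrieval
evaluation on one-sample- and all-samples-per-patient pools, a
visual-acuity linear probe against the random-initialization control, and
the fluid interchange evaluation) completes in a few minutes on one CPU.
The shipping defaults ($d = 512$, 224 x 224, 20 slices, 300 epochs, ratios
80/15/5) mirror the published configuration and are exercised at reduced
sizes only.

Desk-scale runs are exactly reproducible for a fixed master seed but vary
across seeds: over master seeds 1-3 the averaged test top-1 ranged
0.73-0.78 (CLIP) and 0.61-0.65 (CLOOB) against a chance level of 0.027,
and the visual-acuity probe $R^2$ ranged about 0.44-0.65 against ~0 for
random initialization. Single tiny cohorts and 30-epoch budgets carry
irreducible draw-to-draw spread; conclusions should rest on the margins
over chance and over the random-initialization control, which are wide at
every seed, not on any individual decimal.

**Backbones.** The published encoders (ResNet18 and VideoResNet18 with
ImageNet/Kinetics initialization) assume a GPU deep-learning stack and
pretrained weight downloads; here the encoder contract is filled by pooled
dense stacks trained from seeded random initialization, and requesting the
`paper_default` backbone raises an informative error. The embedding-space
interface — shapes, normalization, determinism, checkpointing — is
identical, which is what every downstream stage consumes.

## Numerical choices and degenerate inputs

Row normalization guards norms below 1e-12; `normalize()` maps constant
arrays to zeros via an sd floor; softmax and log-sum-exp are max-shifted;
the leave-one-out log-sum-exp sets the diagonal to $-\infty$ before
shifting. VICReg's variance hinge uses the 1e-4 epsilon inside the square
root, so a fully collapsed batch scores $\mu \cdot 0.99$ per view rather
than $\mu$ exactly. Retrieval ties break toward the lowest index (ties are
measure-zero with float similarities). Thickness measurement counts
supra-threshold voxels (threshold 0.45) in the central depth window
0.32R-0.76R of the middle B-scan, which contains the central band at any
admissible thickness and none of the thin bands.

## Known limitations

* The tiny encoders are linear-friendly by design; tasks requiring deep
  spatial nonlinearity (as real scans would) need the full-scale backbones
  this package does not provide.
* Chance-level behavior of *pretrained-but-unpaired* encoders is modeled by
  the analytic chance level of random embeddings; the published baseline
  row used ImageNet/Kinetics weights that happen to sit at chance.
* Multi-GPU, mixed precision, and distributed sampling are out of scope;
  training is single-process CPU and exactly seed-deterministic.
* Vendor domain shift is rendered (additive offsets) but not corrected.
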