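---
title: "Segmenting the choroid plexus with an atlas-guided patch-based 3-D U-Net: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting the choroid plexus with an atlas-guided patch-based 3-D U-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The choroid plexus is a small, vascularised structure in the brain
ventricles that produces cerebrospinal fluid. Most of its volume sits in
the atria of the lateral ventricles, where it appears as a thin, bright
(on FLAIR) or intermediate-intensity ribbon surrounded by CSF. It is a
difficult automatic segmentation target: it is tiny relative to the head,
its appearance varies across MRI contrasts, and general-purpose
neuroimaging pipelines segment it poorly. plexseg implements an
atlas-guided, patch-based 3-D convolutional segmentation framework for
this structure across three standard anatomical contrasts (T1-weighted,
T2-weighted, FLAIR), together with the evaluation and volumetry
statistics needed to validate such a segmenter and to study plexus volume
across the adult lifespan.

## The segmentation model

**Common space.** All learning happens in a shared "common" (template)
coordinate frame. Subjects carry a rigid `native_transform` (common world
→ native world); volumes are pull-resampled between grids through 4×4
affines with trilinear interpolation for images and nearest-neighbour for
masks (label integrity is enforced: resampling a mask with trilinear
interpolation is an error).

**Probabilistic atlas.** The voxelwise mean of the training masks in
common space. Patch centres for training are drawn from the atlas support
with probability proportional to the atlas value, concentrating patches
where the structure actually occurs; the atlas' dilated bounding box
("crop box") defines the inference region.

**Network.** A compact 3-D U-Net: three encoder blocks of two
(3×3×3 conv, stride 1, pad 1 → batch norm → ReLU) layers, 64 filters in
the first block doubling per block (64, 128, 256); 2×2×2 max pooling
between blocks, the third block acting as the bottleneck (so a 64³ patch
is pooled 64³→32³→16³); a decoder that mirrors the encoder with 2×2×2,
stride-2 transposed convolutions and halving filters (128, 64); and a
1×1×1 head with a hyperbolic-tangent activation, so voxel scores live in
(−1, 1). Two decisions here were genuinely open:

* *Skip connections.* The classical U-Net defines concatenation skips and
  the filter counts above only make sense with them, so they are included
  (a flag disables them for ablation).
* *Bottleneck depth.* "Three blocks" with decoder filters (128, 64) pins
  exactly two pooling stages; the alternative reading (three poolings and
  an implicit 512-filter bottleneck) is inconsistent with the filter
  counts and was rejected.

**Loss.** The generalized Dice loss over the two classes (structure,
background), with class weights `w = 1/(Σr + ε)²` and `ε = 1e-6` guarding
empty-class patches. The tanh scores map to foreground probabilities via
`p = (s+1)/2`. The loss is 0 at a perfect prediction and 1 at the exact
complement, and is differentiable in the scores; training uses ADAM
(default learning rate 1e-4).

**Patching and augmentation.** 64³ patches (41 per subject by default)
centred on atlas-weighted random voxels, fixed per subject per fold and
seeded. Each presentation mirrors the patch across the longitudinal
fissure (the left–right axis of the common grid) with probability 0.5 —
the flip rate is not fixed by the protocol we follow, so it is a
configurable design choice. Patch centres are resampled per fold, not per
epoch.

**Inference.** Deterministic grid tiling of the atlas crop box with
stride half the patch size guarantees full coverage (training-style
atlas-random tiling is available as an option). Overlapping patch scores
are combined by the arithmetic mean; voxels covered by no patch get −1
(the tanh minimum); the mask keeps voxels with mean score strictly
greater than 0, i.e. probability > 0.5. The common-space mask is brought
back to the native grid with the inverse rigid transform and
nearest-neighbour interpolation.

**Experiment design.** 5-fold cross-validation: the shuffled cohort is
cut into five blocks; fold *i* tests on block *i*, validates on the next
block and trains on the remaining three — at n = 50 this is the
(30, 10, 10) design, test sets partition the cohort, and one seeded split
object drives all three contrast models so participant groups are
identical across modalities. Early stopping tracks the validation
generalized Dice loss (patience 15, cap 100 at full scale); the returned
model is the checkpoint with minimum validation loss.

## Evaluation statistics

* **Dice**: `2|A∩B|/(|A|+|B|)`; two empty masks score 1 (agreement on
  absence).
* **HD95**: surface voxels are foreground voxels with a face-neighbour
  outside the mask (grid boundary included); each direction takes the
  95th percentile (linear interpolation, the R default `type = 7`) of
  Euclidean world-space nearest-surface distances, and the reported value
  is the larger direction. The directed-percentile-then-max convention is
  a documented choice — the metric's name alone does not pin it down.
  HD95 of an empty mask is an error, distinct from a geometry mismatch.
* **AUC**: Mann–Whitney formulation with ties counted ½, evaluated inside
  the atlas crop box rather than the whole volume — whole-volume AUC is
  trivially inflated by distant background, so reported values are only
  comparable within this convention.
* **ICC(2,1)**: two-way random effects, absolute agreement, single
  measurement, from the two-way ANOVA mean squares. Absolute agreement
  penalises constant offsets between methods, which is what a volume
  agreement analysis should do.
* **Wilcoxon signed-rank**: zero differences dropped (classical
  convention); exact permutation null over all 2ⁿ sign assignments
  (computed by convolution over doubled midranks) for n ≤ 25, normal
  approximation with tie and continuity corrections beyond.
* **FDR**: Benjamini–Hochberg step-up; all p-values emitted by one
  analysis call are adjusted jointly.
* **Volumetry**: Gaussian GLM with identity link (`volume ~ age + sex +
  tiv`, sex coded F = 0, M = 1). "Generalized linear model" with a
  McFadden pseudo-R² is otherwise underdetermined for a continuous
  response; the Gaussian/identity family makes maximum likelihood
  coincide with least squares and gives well-defined nested
  log-likelihoods (ML variance estimate), so McFadden's `1 − ℓ₁/ℓ₀` is
  0 at the null and grows under genuine signal. Percent change per decade
  is `10·β_age / mean(volume) × 100`, evaluated at the cohort mean volume
  (the customary "≈15% per decade" summary has no other natural
  baseline).

## The phantom cohort

Clinical MRI with expert plexus tracings cannot ship with a package, so
every stage is exercised on synthetic head phantoms:

* an ellipsoidal head (per-subject log-normal size factor, SD 3%);
* two mirrored lateral-ventricle ellipsoids whose semi-axes grow by
  `atrophy_rate = 0.01/yr` beyond age 21 — ventricular enlargement with
  age is the anatomy the atrophy-robustness analysis cares about;
* a bilateral plexus-like curved tube hugging each ventricle's
  posterior-medial wall. Its target volume follows the linear lifespan
  model `V = 0.62 + 0.047·age + 0.30·[male] + ε`, `ε ~ N(0, 0.40²)` cm³,
  truncated below at 0.5 cm³ — the slope and the implied cohort mean
  (≈3.2 cm³ over ages 21–89) are the planted parameters the volumetry
  analysis must recover. The tube radius is bisected on a precomputed
  distance field until the rasterised volume (clipped to the ventricle)
  is within 5% of target;
* modality-specific tissue intensities (CSF dark on T1/FLAIR, bright on
  T2; plexus brighter than CSF on FLAIR, intermediate on T1), a smooth
  second-order polynomial multiplicative bias field (amplitude 0.1),
  additive Gaussian noise (SD 0.03), and a rigid native-space jitter
  (≤5°, ≤3 mm). Structure sizes are fractions of the grid half-extent,
  so one parameter set scales from 32³ test scenes to the 96³ default.

What the phantoms do **not** emulate: cortical anatomy, realistic TIV
(the head is a scaled-down ellipsoid), frond-like plexus morphology,
partial-volume effects at real acquisition resolution, Rician noise,
pathology-specific atrophy, or third/fourth-ventricle plexus components.
Passing tests therefore demonstrate that the pipeline machinery —
sampling, training, stitching, resampling, metrics, statistics — is
correct and recovers planted effects, not that the trained weights would
transfer to clinical images.

## Numerical and implementation choices

* No deep-learning framework exists in this R stack, so the network,
  its gradients and ADAM are implemented from first principles: R
  orchestration over compiled kernels (im2col + BLAS sgemm convolution,
  fused batch-norm+ReLU, pooling, transposed convolution). Network
  arithmetic runs in single precision — gradient checks against finite
  differences agree to the float32 noise floor (~1%), and a tiny network
  overfits a separable batch to Dice 1.0.
* Determinism: every stochastic stage (initialisation, patch centres,
  batching order, flips, phantom draws, splits) derives its seed from a
  user seed; repeated runs are bit-identical, including written NIfTI
  files.
* Batch-norm conv biases are redundant (the normalisation removes them);
  they are kept for the no-batch-norm configuration and receive
  (correctly) zero gradient otherwise.
* Out-of-field voxels are filled with 0 in all resampling; boundary
  patch padding is 0 for images and labels.
* Degenerate inputs fail loudly: empty atlases, empty masks in HD95,
  single-class AUC, rank-deficient designs (with the collinear column
  named), non-finite losses (with the epoch index), plexus target
  volumes that cannot fit inside the ventricles.

## Problem sizes used in the automated studies

The packaged studies are scaled-down analogues chosen to run comfortably
on a single CPU: the segmentation study uses 20 phantoms on 64³ grids
with 5-fold cross-validation and a reduced network (8 base filters, 32³
patches, 8 patches per subject, batch 4, ADAM 2e-3, up to 8 epochs with
patience 3) — on the strongly separable phantom contrasts this
configuration reaches held-out Dice ≈ 0.9 within 3 epochs and ≈ 0.95–0.98
by epoch 8. Overlap saturates early; the later epochs buy volume
calibration: the threshold at score 0 settles, shrinking the per-contrast
volume bias that the absolute-agreement ICC of the cross-modality
analysis is sensitive to. Relatedly, the pipeline applies no per-volume
intensity normalisation: the phantom contrasts share a fixed intensity
scale across subjects, and statistics-based rescaling (evaluated during
development) couples the intensity mapping to ventricle and head size,
which breaks generalisation to anatomically atypical subjects;
harmonising arbitrary clinical intensity scales would be a preprocessing
step outside this package. The FLAIR model runs all five folds; the T1
and T2 models run the first fold of the identical splits for the
cross-modality agreement sample. The lifespan study uses 98 phantoms (masks only; volumes come
from the rasterised truth), and the null-slope false-positive study uses
50 replicate cohorts drawn at the metadata level, where the volume model
is sampled without rasterisation. The full-scale defaults (64 filters,
64³ patches, 41 patches/subject, lr 1e-4, patience 15, cap 100) remain
the package defaults throughout.

## Known limitations

* The reduced network is validated on phantoms only; no claim is made
  about clinical accuracy of any shipped weights (none are shipped).
* Rigid native transforms stand in for the nonlinear template
  registration a clinical pipeline would use; the package's geometry
  layer is exact for the rigid case and is tested as such.
* The Gaussian-GLM reading of the volumetry model is one defensible
  choice among several; coefficients are directly comparable to ordinary
  least squares.
* ICC on small agreement samples (a handful of held-out subjects) is
  reported with its n; it is a smoke-level agreement check at package
  scale, not a population estimate.
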