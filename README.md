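# plexseg

Atlas-guided, patch-based 3-D U-Net segmentation of the choroid plexus
from anatomical MRI contrasts (T1-weighted, T2-weighted, FLAIR), with the
full evaluation and lifespan-volumetry machinery around it — and a
synthetic head-phantom cohort generator so the entire pipeline runs and
is testable without any clinical data.

## Who this is for

Neuroimaging researchers who need to (a) segment a small, bright
intraventricular structure with a patch-based 3-D convolutional network,
(b) validate such a segmenter properly — overlap, surface distance,
voxelwise ROC, method agreement — and (c) relate the resulting volumes to
age, sex and head size across the adult lifespan.

## What is inside

**Model.** A 3-D U-Net with three encoder blocks of two
(3×3×3 conv → batch norm → ReLU) layers, filters 64→128→256, 2×2×2 max
pooling, a mirrored decoder with 2×2×2/stride-2 transposed convolutions
and concatenation skips, and a tanh-activated 1×1×1 head, trained with
the generalized Dice loss

```
L = 1 − 2 · Σ_ℓ w_ℓ Σ_n r_ℓn p_ℓn / Σ_ℓ w_ℓ Σ_n (r_ℓn + p_ℓn),
w_ℓ = 1/(Σ_n r_ℓn + ε)²,  p = (tanh score + 1)/2
```

and ADAM. Training patches (64³, 41 per subject) are centred on random
voxels of a probabilistic atlas — the voxelwise mean of the training
masks in a common space — with random mirroring across the longitudinal
fissure; inference tiles the atlas crop box, averages overlapping patch
scores, thresholds at score > 0, and maps the mask back to native space
by the inverse rigid transform with nearest-neighbour interpolation.
Everything is seeded and bit-reproducible. (No deep-learning framework
exists in this R stack; the network, gradients and optimiser are
implemented in the package, with Rcpp/RcppArmadillo kernels.)

**Evaluation.** Dice-Sørensen coefficient, 95% Hausdorff distance in mm
(directed 95th percentiles of nearest-surface distances, max of the two
directions), voxelwise ROC AUC (Mann–Whitney, ties ½, evaluated in the
atlas crop box), ICC(2,1), Bland–Altman limits of agreement, paired
Wilcoxon signed-rank tests (exact 2ⁿ permutation null for n ≤ 25), and
Benjamini–Hochberg FDR correction. Each statistic is tested against an
independent brute-force oracle.

**Volumetry.** Gaussian GLMs `volume ~ age + sex + tiv` per modality with
Wald tests, joint FDR adjustment, McFadden pseudo-R², and percent volume
change per decade; plus `metrics ~ lateral ventricular volume`
robustness regressions.

**Phantoms.** `generate_cohort()` builds head phantoms with
age-enlarging ventricles and a bilateral plexus-like tube whose volume
follows `V = 0.62 + 0.047·age + 0.30·[male] + N(0, 0.40²)` cm³, painted
with modality-dependent contrasts, bias field, noise and a rigid
native-space jitter.

## Worked example

```r
library(plexseg)

# a 20-subject phantom cohort on a 64^3 common grid
params <- phantom_params(grid_shape = c(64, 64, 64))
cohort <- generate_cohort(params, n = 20, seed = 11)

# reduced network + training schedule (fits a single CPU)
spec   <- train_spec(learning_rate = 2e-3, max_epochs = 8L, patience = 3L,
                     patches_per_subject = 8L, patch_size = 32L, seed = 101L)
netcfg <- unet_config(base_filters = 8L, patch_size = 32L)

# train the first cross-validation fold and score its held-out subjects
splits <- make_cv_splits(cohort$manifest$subject_id, seed = 101L)
one    <- splits; one$folds <- one$folds[1]
scores <- run_cross_validation(cohort, "flair", spec, netcfg,
                               splits = one, atlas_margin = 6L)
print(scores, digits = 3)
#>   subject_id fold  dice hd95_mm   auc vol_pred_cm3 vol_true_cm3
#> 1    sub-003    1 0.978       1 1.000         2.80         2.76
#> 2    sub-009    1 0.983       1 0.999         4.85         4.84
#> 3    sub-014    1 0.990       0 1.000         4.49         4.46
#> 4    sub-017    1 0.981       1 0.999         3.83         3.69
mean(scores$dice)      #> 0.983: held-out overlap with phantom truth
mean(scores$hd95_mm)   #> 0.75 mm: surfaces agree to within one voxel

# lifespan volumetry on a 98-phantom cohort (truth-mask volumes)
life <- generate_cohort(params, 98, seed = 5, detail = "masks")
vols <- data.frame(subject_id = life$manifest$subject_id, modality = "t1",
                   volume_cm3 = sapply(life$subjects,
                                       function(s) mask_volume_cm3(s$truth_mask)))
res <- lifespan_analysis(life$manifest, vols)
res$table[res$table$term == "age", c("estimate", "se", "p_adj")]
#>   estimate      se    p_adj
#> 1   0.0466 0.00199 1.64e-40
res$percent_per_decade   #> 13.9 (% volume increase per decade of life)
```

The Dice/HD95/AUC rows are one fold of the cross-validated evaluation
(running `run_cross_validation()` without the `splits` subsetting covers
all five folds); each held-out subject's predicted volume tracks its
ground truth to within a few percent. The lifespan fit recovers the
generator's planted age slope of 0.047 cm³/yr with its 95% confidence
interval, and the volume-versus-age trend amounts to roughly 14% per
decade of life at the cohort mean volume.

A command-line interface wraps the same functions
(`exec/plexus-seg simulate|build-atlas|train|predict|crossval|evaluate|agree|lifespan`);
every run writes a JSON run-manifest with its configuration and seeds.

## Documentation

The methods vignette (`vignettes/plexseg-methods.Rmd`) describes the
model and its assumptions, the phantom generator and what it does and
does not emulate, every numerically consequential convention (overlap
averaging, thresholding, HD95 percentile, ICC form, zero-difference
handling, FDR scope), and the scaled-down study sizes the automated
checks use.
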