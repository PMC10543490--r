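# Study orchestration: pseudo-randomised 5-fold cross-validation with
# train/validation/test roles, per-modality training from identical splits,
# patch-based training with atlas-weighted sampling and flip augmentation,
# early stopping on the validation generalized Dice loss, and whole-subject
# inference (common-space tiling, stitching, native-space resampling).

#' Cross-validation splits with train/validation/test roles
#'
#' The cohort is shuffled once (seeded) and cut into `n_folds` equal blocks;
#' fold `i` uses block `i` for testing, the next block for validation and
#' the remainder for training, so test sets partition the cohort and each
#' subject is tested exactly once. At `n = 50`, `n_folds = 5` this yields
#' the (30, 10, 10) design. Reuse the same object across modalities to keep
#' participant groups identical.
#'
#' @param ids character vector of subject ids.
#' @param n_folds number of folds (default 5).
#' @param fractions nominal (train, validation, test) fractions; with the
#'   block scheme these are `((n_folds-2)/n_folds, 1/n_folds, 1/n_folds)`
#'   and the argument is validated for consistency.
#' @param seed integer seed.
#' @return Object of class `fold_split`: list of folds, each with `train`,
#'   `val`, `test` id vectors.
#' @export
make_cv_splits <- function(ids, n_folds = 5L, fractions = c(0.6, 0.2, 0.2),
                           seed = 1L) {
  n <- length(ids)
  if (n < n_folds) stopf("%d subjects cannot fill %d folds", n, n_folds)
  if (anyDuplicated(ids)) stopf("duplicate ids in split request")
  if (abs(sum(fractions) - 1) > 1e-8) stopf("fractions must sum to 1")
  shuffled <- with_seed(seed, sample(ids))
  block <- sort(rep(seq_len(n_folds), length.out = n))
  folds <- lapply(seq_len(n_folds), function(i) {
    test <- shuffled[block == i]
    val_block <- if (i == n_folds) 1L else i + 1L
    val <- shuffled[block == val_block]
    list(train = setdiff(shuffled, c(test, val)), val = val, test = test)
  })
  structure(list(folds = folds, n_folds = as.integer(n_folds), seed = seed,
                 ids = ids),
            class = "fold_split")
}

#' Training specification
#'
#' @param learning_rate ADAM learning rate (default 1e-4, the published
#'   setting for the full-size network).
#' @param batch_size patches per optimiser step.
#' @param max_epochs epoch cap.
#' @param patience early-stopping patience on the validation generalized
#'   Dice loss, in epochs.
#' @param patches_per_subject atlas-sampled training patches per subject
#'   (default 41).
#' @param flip_prob probability of mirroring a patch across the
#'   longitudinal fissure at each presentation.
#' @param patch_size cubic patch edge in voxels.
#' @param seed master seed driving initialisation, patch sampling, batching
#'   order and augmentation.
#' @return Object of class `train_spec`.
#' @export
train_spec <- function(learning_rate = 1e-4, batch_size = 4L,
                       max_epochs = 100L, patience = 15L,
                       patches_per_subject = 41L, flip_prob = 0.5,
                       patch_size = 64L, seed = 1L) {
  if (learning_rate <= 0) stopf("learning rate must be positive")
  if (patience > max_epochs) stopf("patience exceeds the epoch cap")
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 patches_per_subject = as.integer(patches_per_subject),
                 flip_prob = flip_prob, patch_size = as.integer(patch_size),
                 seed = as.integer(seed)),
            class = "train_spec")
}

# ---- cohort access -------------------------------------------------------
# A "cohort" is either a cohort_manifest (subjects on disk) or the in-memory
# list returned by generate_cohort(). Subjects are loaded lazily and the
# common-space resampled volumes cached per (id, modality).

cohort_ids <- function(cohort) {
  if (inherits(cohort, "cohort_manifest") || is.data.frame(cohort)) {
    return(cohort$subject_id)
  }
  if (is.list(cohort) && !is.null(cohort$subjects)) {
    return(names(cohort$subjects))
  }
  stopf("cannot interpret cohort object")
}

cohort_subject <- function(cohort, id, modality) {
  if (is.list(cohort) && !is.null(cohort$subjects)) {
    s <- cohort$subjects[[id]]
    if (is.null(s)) stopf("unknown subject '%s'", id)
    if (is.null(s$volumes)) {
      stopf("subject '%s' was generated without intensity volumes", id)
    }
    return(list(volume = s$volumes[[modality]], truth = s$truth_native,
                transform = s$native_transform))
  }
  row <- cohort[cohort$subject_id == id, , drop = FALSE]
  if (nrow(row) != 1L) stopf("unknown subject '%s'", id)
  list(volume = read_volume(row[[paste0(modality, "_path")]]),
       truth = read_volume(row$mask_path, mask = TRUE),
       transform = read_affine(row$transform_path))
}

# Resample a subject's native data into the atlas' common grid. Intensities
# are taken as-is: the training pipeline applies no intensity normalisation
# (phantom contrasts share a fixed scale; harmonising arbitrary clinical
# intensity scales is a preprocessing concern outside this package).
subject_in_common <- function(cohort, id, modality, geom, cache = NULL) {
  key <- paste(id, modality, sep = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  s <- cohort_subject(cohort, id, modality)
  inv <- solve(s$transform)
  img <- resample_with_affine(s$volume, inv, geom, interp = "trilinear",
                              space = "common")
  lbl <- resample_with_affine(s$truth, inv, geom, interp = "nearest",
                              space = "common")
  out <- list(image = img$data, label = lbl$data,
              native_truth = s$truth, transform = s$transform,
              native_volume = s$volume)
  if (!is.null(cache)) cache[[key]] <- out
  out
}

common_geometry_of_atlas <- function(atlas) {
  list(shape = dim(atlas$prob$data), spacing = atlas$prob$spacing,
       affine = atlas$prob$affine)
}

# ---- training ------------------------------------------------------------

#' Train one cross-validation fold
#'
#' Extracts `patches_per_subject` atlas-weighted patches per training and
#' validation subject (fixed per subject, seeded), then optimises the
#' generalized Dice loss with ADAM. Patches are mirrored across the
#' longitudinal fissure with probability `flip_prob` at every presentation.
#' The returned model carries the parameters of the epoch with minimum
#' validation loss and the full per-epoch history.
#'
#' @param cohort a `cohort_manifest` or a [generate_cohort()] result.
#' @param modality `"t1"`, `"t2"` or `"flair"`.
#' @param atlas [build_atlas()] result defining the common grid and the
#'   sampling density.
#' @param fold one element of [make_cv_splits()]`$folds`.
#' @param spec [train_spec()].
#' @param net_config [unet_config()]; its `patch_size` must match `spec`.
#' @param cache optional environment reusing common-space resampled
#'   subjects across folds.
#' @return Trained `unet_model` with `$history` and `$best_epoch`.
#' @export
train_fold <- function(cohort, modality, atlas, fold, spec,
                       net_config = NULL, cache = NULL) {
  stopifnot(inherits(spec, "train_spec"))
  if (is.null(net_config)) {
    net_config <- unet_config(patch_size = spec$patch_size)
  }
  if (net_config$patch_size != spec$patch_size) {
    stopf("net_config patch size %d != train_spec patch size %d",
          net_config$patch_size, spec$patch_size)
  }
  if (sum(atlas$support$data) == 0) stopf("atlas support is empty")
  geom <- common_geometry_of_atlas(atlas)

  load_patches <- function(id) {
    sc <- subject_in_common(cohort, id, modality, geom, cache)
    img <- sc$image
    centers <- sample_patch_centers(atlas, spec$patches_per_subject,
                                    seed = derive_seed(spec$seed, "centers",
                                                       id))
    lapply(seq_len(nrow(centers)), function(i) {
      list(image = extract_patch(img, centers[i, ], spec$patch_size),
           label = extract_patch(sc$label, centers[i, ], spec$patch_size))
    })
  }
  train_patches <- unlist(lapply(fold$train, load_patches), recursive = FALSE)
  val_patches <- unlist(lapply(fold$val, load_patches), recursive = FALSE)
  if (!length(train_patches)) stopf("no training patches")

  model <- build_unet(net_config, seed = derive_seed(spec$seed, "init"))
  opt <- adam_init(model$params)
  ps <- spec$patch_size
  bdims <- function(nb) c(ps, ps, ps, 1L, nb)

  eval_loss <- function(patches) {
    if (!length(patches)) return(NA_real_)
    losses <- numeric(0)
    i <- 1L
    while (i <= length(patches)) {
      j <- min(i + spec$batch_size - 1L, length(patches))
      xs <- vapply(patches[i:j], function(p) as.numeric(p$image),
                   numeric(ps^3))
      ys <- vapply(patches[i:j], function(p) as.numeric(p$label),
                   numeric(ps^3))
      fw <- net_forward(model, as.numeric(xs), bdims(j - i + 1L),
                        training = FALSE)
      losses <- c(losses, gdl_forward(fw$scores, ys)$loss)
      i <- j + 1L
    }
    mean(losses)
  }

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(loss = Inf, params = model$params, running = model$running,
               epoch = 0L)
  wait <- 0L
  rng_seed <- derive_seed(spec$seed, "epochs", modality)
  with_seed(rng_seed, {
    for (epoch in seq_len(spec$max_epochs)) {
      order_ <- sample(length(train_patches))
      epoch_losses <- numeric(0)
      i <- 1L
      while (i <= length(order_)) {
        j <- min(i + spec$batch_size - 1L, length(order_))
        sel <- order_[i:j]
        nb <- length(sel)
        xs <- matrix(0, ps^3, nb)
        ys <- matrix(0, ps^3, nb)
        for (k in seq_len(nb)) {
          p <- train_patches[[sel[k]]]
          if (runif(1) < spec$flip_prob) {
            p <- flip_lr(array(p$image, c(ps, ps, ps)),
                         array(p$label, c(ps, ps, ps)))
            p <- list(image = p$image, label = p$label)
          }
          xs[, k] <- as.numeric(p$image)
          ys[, k] <- as.numeric(p$label)
        }
        fw <- net_forward(model, as.numeric(xs), bdims(nb), training = TRUE)
        model$running <- fw$running
        gf <- gdl_forward(fw$scores, as.numeric(ys))
        if (!is.finite(gf$loss)) {
          stopf("loss became non-finite at epoch %d", epoch)
        }
        epoch_losses <- c(epoch_losses, gf$loss)
        grads <- net_backward(model, fw$cache, gdl_backward(gf))
        st <- adam_step(model$params, grads, opt, spec$learning_rate)
        model$params <- st$params
        opt <- st$state
        i <- j + 1L
      }
      vl <- eval_loss(val_patches)
      history[nrow(history) + 1L, ] <- list(epoch, mean(epoch_losses), vl)
      improved <- is.finite(vl) && vl < best$loss - 1e-6
      if (improved) {
        best <- list(loss = vl, params = model$params,
                     running = model$running, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= spec$patience) break
      }
    }
  })
  model$params <- best$params
  model$running <- best$running
  model$history <- history
  model$best_epoch <- best$epoch
  model$trained <- TRUE
  model
}

# ---- inference -----------------------------------------------------------

# Score a common-space (already normalised) image array with the model.
infer_common_scores <- function(model, image_arr, geom, atlas, spec_or_size,
                                tiling = "grid", seed = 1L) {
  ps <- if (inherits(model, "unet_model")) {
    model$config$patch_size
  } else if (is.numeric(spec_or_size)) {
    as.integer(spec_or_size)
  } else {
    spec_or_size$patch_size
  }
  centers <- if (tiling == "grid") {
    tile_centers(atlas, ps)
  } else {
    sample_patch_centers(atlas, 41L, seed = seed)
  }
  patches <- lapply(seq_len(nrow(centers)), function(i) {
    patch <- extract_patch(image_arr, centers[i, ], ps)
    if (inherits(model, "unet_model")) {
      forward_patch(model, patch)
    } else {
      model(patch, centers[i, ])
    }
  })
  stitch_and_binarize(patches, centers, geom)
}

#' Segment one subject in native space
#'
#' Resamples the native volume to the common (atlas) grid, tiles the atlas
#' crop box with overlapping patches, scores each patch, stitches the
#' overlapping scores (voxelwise mean), binarises at score > 0, and brings
#' the mask back to the native grid with the inverse rigid transform and
#' nearest-neighbour interpolation.
#'
#' @param model trained `unet_model`, or a function `f(patch, center)`
#'   returning a score patch (useful as an oracle in validation studies).
#' @param native_volume [volume3d()] in native space.
#' @param transform 4x4 rigid map, common world -> native world.
#' @param atlas [build_atlas()] result (defines the common grid).
#' @param tiling `"grid"` for deterministic half-patch-stride coverage of
#'   the crop box, `"atlas_random"` for 41 atlas-weighted centres.
#' @param patch_size patch edge when `model` is a plain function.
#' @param seed seed for `"atlas_random"` tiling.
#' @return Native-space [binary_mask3d()]; the common-space score volume is
#'   attached as `attr(, "scores_common")`.
#' @export
predict_subject <- function(model, native_volume, transform, atlas,
                            tiling = c("grid", "atlas_random"),
                            patch_size = NULL, seed = 1L) {
  tiling <- match.arg(tiling)
  geom <- common_geometry_of_atlas(atlas)
  transform <- check_affine(transform)
  common <- resample_with_affine(native_volume, solve(transform), geom,
                                 interp = "trilinear", space = "common")
  img <- common$data
  st <- infer_common_scores(model, img, geom, atlas,
                            patch_size %||% 64L, tiling, seed)
  native_geom <- geometry_of(native_volume)
  mask <- resample_with_affine(st$mask, transform, native_geom,
                               interp = "nearest", space = "native")
  attr(mask, "scores_common") <- st$scores
  mask
}

# ---- cross-validation ----------------------------------------------------

#' Run the full cross-validated experiment for one modality
#'
#' For each fold: build the probabilistic atlas from the fold's training
#' masks, train the network, then segment each held-out test subject and
#' score it against its native-space truth (Dice, 95% Hausdorff in mm) and
#' its common-space truth (voxelwise ROC AUC inside the atlas crop box).
#' Each subject appears exactly once, from the fold where it was tested.
#'
#' @inheritParams train_fold
#' @param splits optional [make_cv_splits()] object; built from
#'   `spec$seed` when absent. Pass the same object across modalities to
#'   keep participant groups identical.
#' @param atlas_margin crop-box margin (voxels) for the per-fold atlas.
#' @param common_geometry grid for atlas building; defaults to the native
#'   grid of the first subject's truth mask, which for phantom cohorts is
#'   the common grid itself.
#' @param model_override optional oracle hook used instead of training
#'   (for pipeline validation): a function taking the subject's
#'   common-space data (list with `image` and `label` arrays) and returning
#'   a patch scorer `f(patch, center)`.
#' @param keep_models return the trained models alongside the score table.
#' @return `data.frame` with columns `subject_id, fold, dice, hd95_mm, auc,
#'   vol_pred_cm3, vol_true_cm3` (and attribute `"models"` if requested).
#' @export
run_cross_validation <- function(cohort, modality, spec, net_config = NULL,
                                 splits = NULL, atlas_margin = 8L,
                                 common_geometry = NULL,
                                 model_override = NULL,
                                 keep_models = FALSE) {
  ids <- cohort_ids(cohort)
  if (is.null(splits)) splits <- make_cv_splits(ids, seed = spec$seed)
  if (!setequal(splits$ids, ids)) stopf("splits do not cover the cohort")
  cache <- new.env(parent = emptyenv())
  # common grid: by construction phantom truths live on the common grid
  if (is.null(common_geometry)) {
    first <- cohort_subject(cohort, ids[1], "t1")
    common_geometry <- geometry_of(first$truth)
  }
  rows <- list()
  models <- list()
  for (f in seq_along(splits$folds)) {
    fold <- splits$folds[[f]]
    train_masks <- lapply(fold$train, function(id) {
      sc <- subject_in_common(cohort, id, modality, common_geometry, cache)
      binary_mask3d(sc$label, common_geometry$spacing,
                    common_geometry$affine, "common")
    })
    atlas <- build_atlas(train_masks, margin = atlas_margin)
    model <- if (is.null(model_override)) {
      fold_spec <- spec
      fold_spec$seed <- derive_seed(spec$seed, "fold", f)
      tryCatch(
        train_fold(cohort, modality, atlas, fold, fold_spec, net_config,
                   cache),
        error = function(e) stopf("fold %d training failed: %s", f,
                                  conditionMessage(e)))
    } else {
      NULL
    }
    if (keep_models) models[[f]] <- model
    for (id in fold$test) {
      sc <- subject_in_common(cohort, id, modality, common_geometry, cache)
      ps <- if (!is.null(net_config)) net_config$patch_size else
        spec$patch_size
      subject_model <- if (is.null(model_override)) {
        model
      } else {
        model_override(sc)
      }
      pred <- predict_subject(subject_model, sc$native_volume,
                              sc$transform, atlas, patch_size = ps)
      truth_native <- sc$native_truth
      scores_common <- attr(pred, "scores_common")
      truth_common <- binary_mask3d(sc$label, common_geometry$spacing,
                                    common_geometry$affine, "common")
      box <- atlas$crop_box
      sel <- function(a) a[(box["lo", 1]:box["hi", 1]) + 1L,
                           (box["lo", 2]:box["hi", 2]) + 1L,
                           (box["lo", 3]:box["hi", 3]) + 1L]
      auc <- roc_auc(as.numeric(sel(scores_common$data)),
                     as.numeric(sel(truth_common$data)))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = id, fold = f,
        dice = dice_coefficient(pred, truth_native),
        hd95_mm = if (sum(pred$data) > 0 && sum(truth_native$data) > 0) {
          hausdorff95(pred, truth_native)
        } else {
          NA_real_
        },
        auc = auc,
        vol_pred_cm3 = mask_volume_cm3(pred),
        vol_true_cm3 = mask_volume_cm3(truth_native),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$subject_id), ]
  rownames(out) <- NULL
  if (keep_models) attr(out, "models") <- models
  out
}
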