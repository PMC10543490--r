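# Cross-validation design, fold training behaviour, and whole-subject
# inference via the oracle pass-through.

test_that("50 ids split into (30, 10, 10) folds that partition the cohort", {
  ids <- sprintf("s%02d", 1:50)
  sp <- make_cv_splits(ids, seed = 4)
  expect_identical(length(sp$folds), 5L)
  for (f in sp$folds) {
    expect_identical(lengths(f[c("train", "val", "test")]),
                     c(train = 30L, val = 10L, test = 10L))
    expect_identical(length(intersect(f$train, f$val)), 0L)
    expect_identical(length(intersect(f$train, f$test)), 0L)
    expect_identical(length(intersect(f$val, f$test)), 0L)
  }
  tests <- unlist(lapply(sp$folds, `[[`, "test"))
  expect_identical(sort(tests), sort(ids))
  expect_identical(anyDuplicated(tests), 0L)
  expect_identical(make_cv_splits(ids, seed = 4), sp)
  expect_false(identical(make_cv_splits(ids, seed = 5), sp))
  expect_error(make_cv_splits(ids[1:3], n_folds = 5), "folds")
})

# a miniature separable training scene shared by the training tests
tiny_training_setup <- function() {
  memo("tiny_training", function() {
    params <- tiny_phantom_params(jitter_max_deg = 2, jitter_max_mm = 1)
    co <- generate_cohort(params, 8, seed = 55)
    splits <- make_cv_splits(co$manifest$subject_id, n_folds = 4L,
                             seed = 55)
    masks <- lapply(splits$folds[[1]]$train, function(id) {
      co$subjects[[id]]$truth_mask
    })
    list(co = co, splits = splits,
         atlas = build_atlas(masks, margin = 4L))
  })
}

tiny_spec <- function(seed = 9L, flip_prob = 0.5, max_epochs = 3L) {
  train_spec(learning_rate = 3e-3, batch_size = 4L,
             max_epochs = max_epochs, patience = max_epochs,
             patches_per_subject = 4L, flip_prob = flip_prob,
             patch_size = 16L, seed = seed)
}

test_that("training reduces the loss and respects its seed", {
  su <- tiny_training_setup()
  cfg <- unet_config(base_filters = 4L, patch_size = 16L)
  fold <- su$splits$folds[[1]]
  m1 <- train_fold(su$co, "flair", su$atlas, fold, tiny_spec(), cfg)
  expect_identical(nrow(m1$history), 3L)
  expect_lt(m1$history$train_loss[3], m1$history$train_loss[1])
  expect_lte(m1$best_epoch, which.min(m1$history$val_loss))
  # identical spec and seed reproduce the selected checkpoint exactly
  m2 <- train_fold(su$co, "flair", su$atlas, fold, tiny_spec(), cfg)
  expect_identical(min(m1$history$val_loss), min(m2$history$val_loss))
  expect_identical(m1$params, m2$params)
  # augmentation is live: disabling flips changes the trajectory
  m3 <- train_fold(su$co, "flair", su$atlas, fold,
                   tiny_spec(flip_prob = 0), cfg)
  expect_false(identical(m3$history$train_loss, m1$history$train_loss))
})

test_that("oracle pass-through predicts truth exactly on aligned phantoms", {
  params <- tiny_phantom_params(jitter_max_deg = 0, jitter_max_mm = 0)
  s <- generate_subject(params, 45, "M", seed = 77)
  atlas <- build_atlas(list(s$truth_mask), margin = 6L)
  oracle <- function(patch, center) {
    2 * extract_patch(s$truth_mask$data, center, dim(patch)[1]) - 1
  }
  pred <- predict_subject(oracle, s$volumes$t1, s$native_transform, atlas,
                          patch_size = 16L)
  expect_identical(pred$data, s$truth_native$data)
  # a constant background oracle yields an empty mask
  empty <- predict_subject(function(patch, center) {
    array(-1, dim(patch))
  }, s$volumes$t1, s$native_transform, atlas, patch_size = 16L)
  expect_identical(sum(empty$data), 0L)
})

test_that("oracle inference survives an integer-translation native space", {
  params <- tiny_phantom_params(jitter_max_deg = 0, jitter_max_mm = 0)
  s <- generate_subject(params, 45, "M", seed = 78)
  tr <- diag(4)
  tr[1:3, 4] <- c(2, -3, 1)
  native_truth <- resample_with_affine(s$truth_mask, tr,
                                       geometry_of(s$truth_mask),
                                       "nearest", space = "native")
  native_vol <- resample_with_affine(s$volumes$t1, tr,
                                     geometry_of(s$volumes$t1),
                                     "trilinear", space = "native")
  atlas <- build_atlas(list(s$truth_mask), margin = 6L)
  oracle <- function(patch, center) {
    2 * extract_patch(s$truth_mask$data, center, dim(patch)[1]) - 1
  }
  pred <- predict_subject(oracle, native_vol, tr, atlas, patch_size = 16L)
  expect_identical(pred$data, native_truth$data)
})

test_that("cross-validation yields one row per subject with sane metrics", {
  su <- tiny_training_setup()
  oracle_factory <- function(sc) {
    lab <- sc$label
    function(patch, center) 2 * extract_patch(lab, center,
                                              dim(patch)[1]) - 1
  }
  scores <- run_cross_validation(su$co, "flair", tiny_spec(),
                                 unet_config(base_filters = 4L,
                                             patch_size = 16L),
                                 splits = su$splits, atlas_margin = 6L,
                                 model_override = oracle_factory)
  expect_identical(nrow(scores), 8L)
  expect_identical(sort(scores$subject_id),
                   sort(su$co$manifest$subject_id))
  expect_identical(anyDuplicated(scores$subject_id), 0L)
  expect_true(all(scores$dice > 0.9))
  expect_true(all(scores$auc > 0.99))
  expect_true(all(scores$hd95_mm <= 2))
  expect_true(all(abs(scores$vol_pred_cm3 - scores$vol_true_cm3) /
                    scores$vol_true_cm3 < 0.1))
})
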