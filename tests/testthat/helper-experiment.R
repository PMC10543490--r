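# The reduced end-to-end study configuration: a scaled-down analogue of the
# full experiment (64^3 phantoms, 5-fold cross-validation, 8-filter network
# on 32^3 patches, 8 atlas patches per subject, ADAM at 2e-3 for up to 8
# epochs). Sized so the whole segmentation analogue runs on one CPU inside
# the test-suite budget; the methods vignette discusses the choice.

reduced_net_config <- function() {
  unet_config(base_filters = 8L, patch_size = 32L)
}

reduced_train_spec <- function(seed) {
  train_spec(learning_rate = 2e-3, batch_size = 4L, max_epochs = 8L,
             patience = 3L, patches_per_subject = 8L, patch_size = 32L,
             seed = as.integer(seed))
}

reduced_cohort <- function() {
  memo("reduced_cohort", function() {
    generate_cohort(phantom_params(grid_shape = c(64, 64, 64)), 20,
                    seed = 20260101L)
  })
}

reduced_splits <- function() {
  make_cv_splits(reduced_cohort()$manifest$subject_id, seed = 77L)
}

# Cross-validated score tables per modality. The primary modality runs all
# five folds; the other two run the first two folds (their test subjects
# give the cross-modality agreement sample), reusing identical splits.
reduced_cv_scores <- function(modality, folds = NULL) {
  key <- paste0("cv_", modality)
  memo(key, function() {
    co <- reduced_cohort()
    splits <- reduced_splits()
    if (!is.null(folds)) {
      splits$folds <- splits$folds[folds]
    }
    run_cross_validation(co, modality, reduced_train_spec(1234L),
                         reduced_net_config(), splits = splits,
                         atlas_margin = 6L)
  })
}
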