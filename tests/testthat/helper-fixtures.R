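# Shared fixtures. Everything is generated in code; heavyweight objects are
# memoised in `.fixture_env` so several test files can share one instance.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# A small phantom parameter set for unit tests: a 32^3 scene with a
# miniature plexus so the tube fits inside small ventricles. Study-scale
# tests use phantom_params() defaults instead.
tiny_phantom_params <- function(...) {
  args <- list(grid_shape = c(32, 32, 32), vol_beta0 = 0.25,
               vol_beta_age = 0.003, vol_beta_male = 0.05,
               vol_sigma = 0.03, min_volume_cm3 = 0.1)
  do.call(phantom_params, utils::modifyList(args, list(...)))
}

tiny_subject <- function() {
  memo("tiny_subject", function() {
    generate_subject(tiny_phantom_params(), age = 50, sex = "F", seed = 42)
  })
}

# cubic ball mask, ~n_voxels large, for resampling/metric fixtures
ball_mask <- function(shape = c(40, 40, 40), radius = 6.2,
                      spacing = c(1, 1, 1)) {
  cs <- lapply(seq_len(3), function(a) {
    (seq_len(shape[a]) - (shape[a] + 1) / 2) * spacing[a]
  })
  r2 <- outer(outer(cs[[1]]^2, cs[[2]]^2, "+"), cs[[3]]^2, "+")
  binary_mask3d(r2 <= radius^2, spacing = spacing)
}

random_mask <- function(shape = c(6, 6, 6), p = 0.4,
                        spacing = c(1, 1, 1)) {
  m <- array(stats::rbinom(prod(shape), 1, p), shape)
  if (sum(m) == 0) m[sample(length(m), 1)] <- 1
  binary_mask3d(m, spacing = spacing)
}

expect_same_mask <- function(a, b) {
  expect_identical(a$data, b$data)
}
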