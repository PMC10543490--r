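# The synthetic cohort generator: determinism, anatomy invariants, the
# planted lifespan volume model, and manifest consistency.

test_that("subjects are deterministic and anatomically nested", {
  s <- tiny_subject()
  s2 <- generate_subject(tiny_phantom_params(), age = 50, sex = "F",
                         seed = 42)
  expect_identical(s$truth_mask$data, s2$truth_mask$data)
  expect_identical(s$volumes$flair$data, s2$volumes$flair$data)
  expect_identical(s$native_transform, s2$native_transform)
  # truth within ventricles within head, and bilateral
  expect_true(all(s$truth_mask$data <= s$ventricle_mask$data))
  expect_true(all(s$ventricle_mask$data <= s$head_mask$data))
  half <- dim(s$truth_mask$data)[1] %/% 2
  expect_gt(sum(s$truth_mask$data[1:half, , ]), 0)
  expect_gt(sum(s$truth_mask$data[(half + 1):(2 * half), , ]), 0)
})

test_that("rasterised plexus volume hits its target within 5%", {
  for (seed in 1:5) {
    s <- generate_subject(tiny_phantom_params(), age = 30 + 10 * seed,
                          sex = c("F", "M")[1 + seed %% 2], seed = seed,
                          detail = "masks")
    expect_lt(abs(s$meta$achieved_volume_cm3 - s$meta$target_volume_cm3) /
                s$meta$target_volume_cm3, 0.05)
    expect_lt(abs(mask_volume_cm3(s$truth_mask) -
                    s$meta$achieved_volume_cm3), 1e-9)
  }
})

test_that("volume model: 64-year age gap shows up as beta_age * 64", {
  p <- phantom_params(grid_shape = c(64, 64, 64), vol_sigma = 0)
  young <- generate_subject(p, 21, "F", seed = 7, detail = "masks")
  old <- generate_subject(p, 85, "F", seed = 7, detail = "masks")
  gap <- old$meta$achieved_volume_cm3 - young$meta$achieved_volume_cm3
  expect_lt(abs(gap - 0.047 * 64) / (0.047 * 64), 0.05)
})

test_that("ventricles enlarge with age; volumes match manifest within 5%", {
  p <- tiny_phantom_params()
  lvv <- sapply(c(25, 50, 80), function(a) {
    generate_subject(p, a, "M", seed = 11, detail = "masks")$meta$lvv_cm3
  })
  expect_true(all(diff(lvv) > 0))
  s <- generate_subject(p, 50, "M", seed = 11, detail = "masks")
  expect_lt(abs(mask_volume_cm3(s$ventricle_mask) - s$meta$lvv_cm3) /
              s$meta$lvv_cm3, 0.05)
  expect_lt(abs(mask_volume_cm3(s$head_mask) - s$meta$tiv_cm3) /
              s$meta$tiv_cm3, 0.05)
})

test_that("modality contrasts behave like the tissue table", {
  s <- tiny_subject()
  common_geom <- geometry_of(s$truth_mask)
  for (mod in c("t1", "t2", "flair")) {
    vol <- resample_with_affine(s$volumes[[mod]],
                                solve(s$native_transform), common_geom,
                                "trilinear")
    plex <- mean(vol$data[s$truth_mask$data == 1])
    csf <- mean(vol$data[s$ventricle_mask$data == 1 &
                           s$truth_mask$data == 0])
    if (mod == "t2") expect_gt(csf, plex) else expect_gt(plex, csf)
  }
})

test_that("unreachable plexus volumes fail with a helpful error", {
  p <- tiny_phantom_params(vol_beta0 = 60, vol_sigma = 0)
  expect_error(generate_subject(p, 50, "F", seed = 1, detail = "masks"),
               "ventricles")
  expect_error(generate_subject(tiny_phantom_params(), 12, "F", seed = 1),
               "outside")
})

test_that("cohorts have unique ids, valid manifests and uniform ages", {
  co <- generate_cohort(tiny_phantom_params(), 12, seed = 3,
                        detail = "masks")
  expect_identical(length(unique(co$manifest$subject_id)), 12L)
  expect_true(all(co$manifest$age >= 21 & co$manifest$age <= 89))
  expect_true(all(co$manifest$sex %in% c("F", "M")))
  co2 <- generate_cohort(tiny_phantom_params(), 12, seed = 3,
                         detail = "masks")
  expect_identical(co$manifest$plexus_cm3, co2$manifest$plexus_cm3)
})

test_that("an OLS fit on generated volumes recovers the planted slope", {
  p <- phantom_params(grid_shape = c(64, 64, 64))
  co <- generate_cohort(p, 98, seed = 31, detail = "masks")
  m <- co$manifest
  fit <- stats::lm(plexus_cm3 ~ age + I(sex == "M"), data = m)
  ci <- stats::confint(fit)["age", ]
  expect_true(ci[1] <= p$vol_beta_age && p$vol_beta_age <= ci[2])
})

test_that("large-cohort mean volume matches the model expectation", {
  p <- tiny_phantom_params()
  co <- generate_cohort(p, 200, seed = 8, detail = "metadata")
  mu_expect <- p$vol_beta0 + p$vol_beta_age * 55 + p$vol_beta_male * 0.5
  se <- sqrt(stats::var(co$manifest$plexus_cm3) / 200)
  expect_lt(abs(mean(co$manifest$plexus_cm3) - mu_expect), 3 * se)
})

test_that("anisotropic FLAIR grids carry the requested spacing", {
  s <- generate_subject(tiny_phantom_params(), 40, "M", seed = 2,
                        aniso_flair = TRUE)
  expect_equal(s$volumes$flair$spacing, c(0.57, 0.57, 4.0))
  expect_equal(s$volumes$t1$spacing, c(1, 1, 1))
  # 100 voxels at that spacing are 0.12996 cm^3
  m <- binary_mask3d(array(rep(c(1, 0), c(100, 28)), c(8, 8, 2)),
                     spacing = c(0.57, 0.57, 4.0))
  expect_equal(mask_volume_cm3(m), 100 * 0.57 * 0.57 * 4 / 1000)
})

test_that("intensity-table validation enforces plexus/CSF separability", {
  bad <- rbind(t1 = c(parenchyma = 0.6, csf = 0.45, plexus = 0.5,
                      background = 0),
               t2 = c(0.4, 0.9, 0.6, 0),
               flair = c(0.5, 0.1, 0.7, 0))
  expect_error(tiny_phantom_params(intensities = bad), "gap")
})
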