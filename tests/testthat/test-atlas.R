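# Probabilistic atlas, patch sampling, flip augmentation and stitching.

make_mask <- function(fill) {
  a <- array(0, c(12, 12, 12))
  fill(a)
}

test_that("atlas probability is the voxelwise mean with dilated crop box", {
  m1 <- binary_mask3d({a <- array(0, c(12, 12, 12)); a[3:5, 3:5, 3:5] <- 1; a})
  m2 <- binary_mask3d({a <- array(0, c(12, 12, 12)); a[8:9, 8:9, 8:9] <- 1; a})
  one <- build_atlas(list(m1), margin = 0L)
  expect_identical(one$prob$data, m1$data + 0)
  expect_identical(one$crop_box["lo", ], c(2L, 2L, 2L))
  expect_identical(one$crop_box["hi", ], c(4L, 4L, 4L))
  both <- build_atlas(list(m1, m2), margin = 2L)
  expect_true(all(both$prob$data[m1$data == 1] == 0.5))
  expect_true(all(both$prob$data[m2$data == 1] == 0.5))
  expect_identical(sum(both$prob$data > 0), sum(m1$data) + sum(m2$data))
  expect_identical(both$crop_box["lo", ], c(0L, 0L, 0L))
  expect_identical(both$crop_box["hi", ], c(10L, 10L, 10L))
  # support contains every contributing mask
  expect_true(all(both$support$data >= m1$data))
  expect_true(all(both$support$data >= m2$data))
})

test_that("atlas building rejects inconsistent input", {
  m1 <- binary_mask3d(array(0, c(12, 12, 12)))
  expect_error(build_atlas(list(m1)), "empty")
  m2 <- binary_mask3d(array(1, c(10, 10, 10)))
  m3 <- binary_mask3d(array(1, c(12, 12, 12)))
  expect_error(build_atlas(list(m3, m2)), "geometry")
})

test_that("patch centres are atlas-weighted, in-support and seeded", {
  atlas <- build_atlas(list(tiny_subject()$truth_mask), margin = 4L)
  cs <- sample_patch_centers(atlas, seed = 9)
  expect_identical(nrow(cs), 41L)
  probs <- apply(cs, 1, function(cc) {
    atlas$prob$data[cc[1] + 1, cc[2] + 1, cc[3] + 1]
  })
  expect_true(all(probs > 0))
  expect_identical(sample_patch_centers(atlas, seed = 9), cs)
  expect_false(identical(sample_patch_centers(atlas, seed = 10), cs))
})

test_that("extract_patch crops, pads and validates", {
  set.seed(2)
  arr <- array(rnorm(20^3), c(20, 20, 20))
  inner <- extract_patch(arr, c(10, 10, 10), size = 8)
  expect_identical(dim(inner), c(8L, 8L, 8L))
  expect_identical(inner, arr[7:14, 7:14, 7:14])  # centre at patch index 4
  corner <- extract_patch(arr, c(0, 0, 0), size = 8, pad_value = -7)
  expect_identical(dim(corner), c(8L, 8L, 8L))
  # analytic pad count: 4 of 8 entries clipped per axis
  expect_equal(sum(corner == -7), 8^3 - 4^3)
  expect_identical(corner[5:8, 5:8, 5:8], arr[1:4, 1:4, 1:4])
  cst <- extract_patch(array(3, c(6, 6, 6)), c(3, 3, 3), size = 8)
  expect_equal(sum(cst == 3), 6^3)
  expect_equal(sum(cst == 0), 8^3 - 6^3)
  expect_error(extract_patch(arr, c(25, 0, 0), 8), "outside")
})

test_that("flip_lr is an involution that mirrors the left-right axis", {
  set.seed(4)
  img <- array(rnorm(6^3), c(6, 6, 6))
  lbl <- array(0, c(6, 6, 6))
  lbl[2, 3, 4] <- 1
  once <- flip_lr(img, lbl)
  twice <- flip_lr(once$image, once$label)
  expect_identical(twice$image, img)
  expect_identical(twice$label, lbl)
  expect_identical(which(once$label == 1, arr.ind = TRUE)[1, ],
                   c(dim1 = 5L, dim2 = 3L, dim3 = 4L))
  expect_error(flip_lr(img, array(0, c(5, 6, 6))), "shapes")
  # a mid-sagittally symmetric mask is flip-invariant (Dice 1)
  sym <- tiny_subject()$truth_mask
  fl <- flip_lr(sym$data * 1.0)$image
  flm <- binary_mask3d(fl, sym$spacing, sym$affine)
  expect_gt(dice_coefficient(sym, flm), 0.95)
})

test_that("stitching averages overlaps, fills -1, thresholds strictly", {
  g <- list(shape = c(16L, 16L, 16L), spacing = c(1, 1, 1),
            affine = centered_affine(c(16, 16, 16), c(1, 1, 1)))
  patch <- array(0.5, c(4, 4, 4))
  one <- stitch_and_binarize(list(patch), rbind(c(8, 8, 8)), g)
  expect_identical(sum(one$mask$data), 64L)
  expect_identical(one$scores$data[1, 1, 1], -1)
  # n identical patches are idempotent
  many <- stitch_and_binarize(rep(list(patch), 5),
                              matrix(rep(c(8, 8, 8), 5), ncol = 3,
                                     byrow = TRUE), g)
  expect_identical(many$scores$data, one$scores$data)
  # opposite scores cancel; strict > excludes the tie voxel
  pos <- array(0.5, c(4, 4, 4))
  neg <- array(-0.5, c(4, 4, 4))
  mix <- stitch_and_binarize(list(pos, neg),
                             rbind(c(8, 8, 8), c(8, 8, 8)), g)
  expect_identical(sum(mix$mask$data), 0L)
  expect_true(all(mix$scores$data[9, 9, 9] == 0))
  # patch order does not matter
  p2 <- array(0.25, c(4, 4, 4))
  a <- stitch_and_binarize(list(pos, p2), rbind(c(6, 6, 6), c(9, 9, 9)), g)
  b <- stitch_and_binarize(list(p2, pos), rbind(c(9, 9, 9), c(6, 6, 6)), g)
  expect_identical(a$scores$data, b$scores$data)
  expect_identical(a$mask$data, b$mask$data)
  expect_error(stitch_and_binarize(list(), matrix(0, 0, 3), g), "empty")
})

test_that("sample-extract-stitch reproduces labels on patch footprints", {
  s <- tiny_subject()
  atlas <- build_atlas(list(s$truth_mask), margin = 4L)
  centers <- sample_patch_centers(atlas, n = 10, seed = 13)
  lab <- s$truth_mask$data
  patches <- lapply(seq_len(nrow(centers)), function(i) {
    2 * extract_patch(lab, centers[i, ], size = 16) - 1
  })
  st <- stitch_and_binarize(patches, centers, geometry_of(s$truth_mask))
  covered <- st$scores$data > -1
  expect_identical(st$mask$data[covered], lab[covered])
  expect_true(all(st$mask$data[!covered] == 0))
})

test_that("atlas persists through NIfTI + JSON sidecar", {
  atlas <- build_atlas(list(tiny_subject()$truth_mask,
                            tiny_subject()$ventricle_mask), margin = 3L)
  f <- tempfile(fileext = ".nii.gz")
  write_atlas(atlas, f)
  back <- read_atlas(f)
  expect_identical(back$crop_box, atlas$crop_box)
  expect_identical(back$margin, atlas$margin)
  expect_lt(max(abs(back$prob$data - atlas$prob$data)), 1e-7)
})
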