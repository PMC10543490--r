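# Segmentation and agreement statistics against brute-force oracles.

test_that("Dice handles identity, disjoint, shifted and empty cases", {
  cube <- function(lo) {
    a <- array(0, c(8, 8, 8))
    a[lo[1]:(lo[1] + 1), lo[2]:(lo[2] + 1), lo[3]:(lo[3] + 1)] <- 1
    binary_mask3d(a)
  }
  a <- cube(c(3, 3, 3))
  expect_identical(dice_coefficient(a, a), 1)
  expect_identical(dice_coefficient(a, cube(c(6, 6, 6))), 0)
  shifted <- cube(c(4, 3, 3))  # overlap is a 1x2x2 slab
  expect_identical(dice_coefficient(a, shifted), 0.5)
  expect_identical(dice_coefficient(shifted, a), 0.5)
  empty <- binary_mask3d(array(0, c(8, 8, 8)))
  expect_identical(dice_coefficient(empty, empty), 1)
  expect_identical(dice_coefficient(a, empty), 0)
  expect_error(dice_coefficient(a, binary_mask3d(array(0, c(6, 6, 6)))),
               "geometry")
  set.seed(10)
  for (i in 1:50) {
    m1 <- random_mask()
    m2 <- random_mask()
    expect_equal(dice_coefficient(m1, m2), oracle_dice(m1, m2),
                 tolerance = 1e-12)
    expect_identical(dice_coefficient(m1, m2), dice_coefficient(m2, m1))
  }
})

test_that("HD95 matches single-voxel arithmetic and spacing scaling", {
  single <- function(at, spacing = c(1, 1, 1)) {
    a <- array(0, c(8, 8, 8))
    a[at[1], at[2], at[3]] <- 1
    binary_mask3d(a, spacing = spacing)
  }
  a <- single(c(1, 1, 1))
  expect_identical(hausdorff95(a, a), 0)
  expect_equal(hausdorff95(a, single(c(4, 1, 1))), 3)
  expect_equal(hausdorff95(single(c(1, 1, 1), c(2, 1, 1)),
                           single(c(4, 1, 1), c(2, 1, 1))), 6)
  expect_error(hausdorff95(a, binary_mask3d(array(0, c(8, 8, 8)))),
               "empty")
})

test_that("HD95 agrees with the all-pairs oracle on random fixtures", {
  set.seed(11)
  for (i in 1:100) {
    sp <- sample(list(c(1, 1, 1), c(0.5, 1, 2)), 1)[[1]]
    m1 <- random_mask(c(6, 6, 6), p = 0.35, spacing = sp)
    m2 <- random_mask(c(6, 6, 6), p = 0.35, spacing = sp)
    got <- hausdorff95(m1, m2)
    expect_equal(got, oracle_hd95(m1, m2), tolerance = 1e-9)
    # bounded by the classical (100th percentile) Hausdorff distance
    expect_lte(got, hausdorff95(m1, m2, percentile = 1) + 1e-12)
  }
})

test_that("AUC equals the Mann-Whitney pair count with half ties", {
  expect_identical(roc_auc(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_identical(roc_auc(rep(0.3, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.7, 0.8, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "one class")
  set.seed(12)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)
    # invariant under strictly monotone transforms of the scores
    expect_equal(roc_auc(exp(3 * scores), labels),
                 roc_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("ICC(2,1) matches the explicit ANOVA oracle", {
  x <- matrix(c(1, 2, 3, 4, 1, 2, 3, 4), ncol = 2)
  expect_equal(icc(x), 1, tolerance = 1e-12)
  offset <- cbind(x[, 1], x[, 1] + 10)
  expect_lt(icc(offset), 1)  # absolute agreement penalises offsets
  expect_error(icc(x[1:2, ]), "at least 3")
  expect_error(icc(matrix(5, 4, 3)), "zero variance")
  expect_error(icc(cbind(c(1, NA, 3), c(1, 2, 3))), "missing")
  set.seed(13)
  for (i in 1:100) {
    m <- matrix(rnorm(18, sd = 2) + rep(rnorm(6), 3), 6, 3)
    expect_equal(icc(m), oracle_icc21(m), tolerance = 1e-10)
  }
})

test_that("Bland-Altman bias and limits follow the hand arithmetic", {
  z <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_identical(unlist(z), c(bias = 0, sd_diff = 0, loa_low = 0,
                                loa_high = 0))
  o <- bland_altman(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_equal(unlist(o), c(bias = 1, sd_diff = 0, loa_low = 1,
                            loa_high = 1))
  t2 <- bland_altman(c(1, 3), c(1, 1))
  expect_equal(t2$bias, 1)
  expect_equal(t2$sd_diff, sqrt(2))
  expect_equal(t2$loa_low, 1 - 1.96 * sqrt(2))
  expect_equal(t2$loa_high, 1 + 1.96 * sqrt(2))
  expect_error(bland_altman(1:3, 1:4), "length")
  set.seed(14)
  for (i in 1:30) {
    x <- rnorm(10)
    y <- rnorm(10)
    b <- bland_altman(x, y)
    expect_equal(b$loa_low, b$bias - 1.96 * b$sd_diff, tolerance = 1e-12)
    expect_equal(b$loa_high, b$bias + 1.96 * b$sd_diff, tolerance = 1e-12)
  }
})

test_that("Wilcoxon exact p equals the 2^n enumeration oracle", {
  w <- wilcoxon_signed_rank(c(2, 4, 6), c(1, 2, 3))
  expect_identical(w$statistic, 6)  # all ranks positive, W- = 0
  expect_equal(w$p_value, 0.25, tolerance = 1e-12)
  deg <- wilcoxon_signed_rank(1:4, 1:4)
  expect_true(deg$degenerate)
  expect_identical(deg$p_value, 1)
  set.seed(15)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    x <- round(rnorm(n), 1)
    y <- round(rnorm(n), 1)  # rounding forces occasional ties and zeros
    got <- wilcoxon_signed_rank(x, y)
    expect_equal(got$p_value, oracle_wilcoxon_p(x, y), tolerance = 1e-12)
    expect_true(got$exact)
  }
  # beyond the exact limit the normal approximation takes over
  set.seed(16)
  big <- wilcoxon_signed_rank(rnorm(40), rnorm(40))
  expect_false(big$exact)
  expect_true(big$p_value > 0 && big$p_value <= 1)
})

test_that("FDR adjustment reproduces the step-up rule", {
  expect_identical(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  expect_equal(fdr_adjust(c(0.005, 0.04)), c(0.01, 0.04),
               tolerance = 1e-12)
  expect_error(fdr_adjust(c(0.1, 1.2)), "0, 1")
  set.seed(17)
  for (i in 1:100) {
    p <- runif(sample(2:12, 1))
    adj <- fdr_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    # monotone: adjusted values preserve the ordering of the raw ones
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(18)
  for (i in 1:5) {
    labels <- c(0, 1, rbinom(40, 1, 0.4))
    scores <- rnorm(42) + labels
    ref <- as.numeric(suppressMessages(pROC::auc(labels, scores,
                                                 direction = "<")))
    expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
  }
})
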