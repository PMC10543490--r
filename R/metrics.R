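# Segmentation performance and method-agreement statistics: Dice overlap,
# 95% Hausdorff surface distance (mm), voxelwise ROC AUC, ICC(2,1),
# Bland-Altman limits of agreement, the paired Wilcoxon signed-rank test
# (exact permutation null for small samples) and Benjamini-Hochberg FDR
# adjustment.

#' Dice-Sorensen overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks agree perfectly and score 1.
#'
#' @param a,b [binary_mask3d()] objects with identical geometry.
#' @return Scalar in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  stopifnot_same_geometry(a, b, "masks")
  na <- sum(a$data)
  nb <- sum(b$data)
  if (na + nb == 0) return(1)
  2 * sum(a$data * b$data) / (na + nb)
}

# Surface voxels: foreground voxels with at least one face-neighbour outside
# the mask, voxels on the grid boundary included.
surface_voxels <- function(mask) {
  m <- mask$data > 0
  d <- dim(m)
  interior <- array(TRUE, d)
  shift_ok <- function(ax, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(seq_len(3), function(a) seq_len(d[a]))
    idx_dst <- idx_src
    if (by > 0) {
      idx_dst[[ax]] <- seq_len(d[ax] - 1)
      idx_src[[ax]] <- 2:d[ax]
    } else {
      idx_dst[[ax]] <- 2:d[ax]
      idx_src[[ax]] <- seq_len(d[ax] - 1)
    }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (ax in 1:3) {
    for (by in c(-1, 1)) interior <- interior & shift_ok(ax, by)
  }
  surf <- m & !interior
  idx <- which(surf, arr.ind = TRUE)
  # world coordinates via the affine (0-based indices)
  homo <- cbind(idx - 1, 1)
  t(mask$affine %*% t(homo))[, 1:3, drop = FALSE]
}

#' 95% Hausdorff distance between mask surfaces (mm)
#'
#' For each direction, the 95th percentile (linear interpolation) of the
#' Euclidean world-space distances from every surface voxel of one mask to
#' the nearest surface voxel of the other; the reported value is the larger
#' of the two directed distances.
#'
#' @param a,b non-empty [binary_mask3d()] objects with identical geometry.
#' @param percentile percentile of the directed surface distances
#'   (default 0.95).
#' @return Distance in mm.
#' @export
hausdorff95 <- function(a, b, percentile = 0.95) {
  stopifnot_same_geometry(a, b, "masks")
  if (sum(a$data) == 0 || sum(b$data) == 0) {
    stopf("Hausdorff distance is undefined for an empty mask")
  }
  sa <- surface_voxels(a)
  sb <- surface_voxels(b)
  dab <- quantile(nn_min_dists(sa, sb), percentile, type = 7, names = FALSE)
  dba <- quantile(nn_min_dists(sb, sa), percentile, type = 7, names = FALSE)
  max(dab, dba)
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a randomly chosen positive voxel outranks a
#' randomly chosen negative one, ties counted one half. For segmentation
#' evaluation, scores come from the stitched score volume restricted to the
#' atlas crop box and labels from the ground truth.
#'
#' @param scores numeric vector of voxel scores.
#' @param labels binary vector (both classes must be present).
#' @return Scalar in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stopf("length mismatch")
  if (any(labels != 0 & labels != 1)) stopf("labels must be binary")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stopf("AUC is undefined when only one class is present")
  }
  r <- rank(scores)  # midranks
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement:
#' `(MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))` from the
#' two-way ANOVA mean squares (rows = subjects, columns = methods).
#'
#' @param measurements n x k numeric matrix, n >= 3 subjects, k >= 2
#'   methods, no missing cells.
#' @return Scalar in \[-1, 1\].
#' @export
icc <- function(measurements) {
  x <- as.matrix(measurements)
  n <- nrow(x)
  k <- ncol(x)
  if (n < 3 || k < 2) stopf("ICC needs at least 3 subjects and 2 methods")
  if (anyNA(x)) stopf("ICC input has missing cells")
  gm <- mean(x)
  if (max(abs(x - gm)) < 1e-300) stopf("ICC undefined: zero variance")
  rm_ <- rowMeans(x)
  cm <- colMeans(x)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sst <- sum((x - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Bland-Altman agreement statistics
#'
#' Differences `d = x - y`; bias is their mean, the limits of agreement are
#' `bias +/- 1.96 * SD(d)` (sample SD, n-1 denominator).
#'
#' @param x,y paired measurement vectors of equal length >= 2.
#' @return list with `bias`, `sd_diff`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stopf("paired vectors differ in length")
  if (length(x) < 2) stopf("need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, sd_diff = s, loa_low = bias - 1.96 * s,
       loa_high = bias + 1.96 * s)
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Zero differences are dropped (classical Wilcoxon convention). For `n <=
#' exact_limit` remaining pairs the two-sided p-value comes from the exact
#' permutation null over all 2^n sign assignments of the (mid)ranks,
#' computed by convolution; beyond that a normal approximation with tie and
#' continuity corrections is used.
#'
#' @param x,y paired numeric vectors.
#' @param exact_limit largest n for the exact null (default 25).
#' @return list with `statistic` (W+, the positive-rank sum), `p_value`,
#'   `exact` flag and `degenerate` flag (all differences zero -> p = 1).
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 25L) {
  if (length(x) != length(y)) stopf("paired vectors differ in length")
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) {
    return(list(statistic = 0, p_value = 1, exact = TRUE, degenerate = TRUE))
  }
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_limit) {
    # distribution of W+ over equiprobable sign patterns; double the ranks
    # so midranks become integers
    r2 <- as.integer(round(2 * r))
    counts <- numeric(sum(r2) + 1)  # index i -> doubled statistic i-1
    counts[1] <- 1
    for (q in r2) {
      shifted <- c(numeric(q), counts[seq_len(length(counts) - q)])
      counts <- counts + shifted
    }
    tot <- 2^n
    w2 <- round(2 * w)
    p_le <- sum(counts[seq_len(w2 + 1)]) / tot
    p_ge <- sum(counts[(w2 + 1):length(counts)]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(statistic = w, p_value = p, exact = TRUE,
                degenerate = FALSE))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w - mu - 0.5 * sign(w - mu)) / sqrt(sigma2)
  list(statistic = w, p_value = min(1, 2 * pnorm(-abs(z))), exact = FALSE,
       degenerate = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up rule: sort ascending, `q_(i) = min_{j >= i} p_(j) * m / j`,
#' capped at 1, mapped back to the input order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
fdr_adjust <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (any(!is.finite(pvals) | pvals < 0 | pvals > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Score one predicted segmentation against truth
#'
#' @param pred,truth native-space masks with identical geometry.
#' @param scores optional common-space score [volume3d()].
#' @param truth_common,atlas optional common-space truth and atlas; with
#'   `scores` present, AUC is computed over the atlas crop box.
#' @return list with `dice`, `hd95_mm` and (if scores given) `auc`.
#' @export
seg_scores <- function(pred, truth, scores = NULL, truth_common = NULL,
                       atlas = NULL) {
  out <- list(dice = dice_coefficient(pred, truth),
              hd95_mm = if (sum(pred$data) > 0 && sum(truth$data) > 0) {
                hausdorff95(pred, truth)
              } else {
                NA_real_
              })
  if (!is.null(scores) && !is.null(truth_common) && !is.null(atlas)) {
    box <- atlas$crop_box
    sel <- function(a) a[(box["lo", 1]:box["hi", 1]) + 1L,
                         (box["lo", 2]:box["hi", 2]) + 1L,
                         (box["lo", 3]:box["hi", 3]) + 1L]
    out$auc <- roc_auc(as.numeric(sel(scores$data)),
                       as.numeric(sel(truth_common$data)))
  }
  out
}
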