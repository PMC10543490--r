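# Probabilistic atlas of the structure in common space, patch sampling
# weighted by the atlas, flip augmentation, and stitching of overlapping
# patch predictions back into a volume. Patch centres are 0-based voxel
# indices; a patch of even size s centred at c covers indices
# [c - s/2, c + s/2 - 1] along each axis.

#' Build a probabilistic atlas from aligned masks
#'
#' The atlas probability is the voxelwise mean of the training masks; its
#' support is every voxel with nonzero probability, and the crop box is the
#' support bounding box dilated by `margin` voxels (clipped to the grid).
#'
#' @param masks list of [binary_mask3d()] in common space with identical
#'   geometry.
#' @param margin dilation of the support bounding box, in voxels.
#' @return Object of class `prob_atlas` with fields `prob` ([volume3d()]),
#'   `support` ([binary_mask3d()]), `crop_box` (2x3 matrix of 0-based
#'   inclusive bounds) and `margin`.
#' @export
build_atlas <- function(masks, margin = 8L) {
  if (!length(masks)) stopf("build_atlas: need at least one mask")
  for (m in masks) {
    if (!is_mask(m)) stopf("build_atlas: all inputs must be binary masks")
    stopifnot_same_geometry(masks[[1]], m, "atlas masks")
  }
  shape <- dim(masks[[1]]$data)
  acc <- array(0, shape)
  for (m in masks) acc <- acc + m$data
  prob <- acc / length(masks)
  if (!any(prob > 0)) stopf("build_atlas: all masks are empty")
  support <- prob > 0
  idx <- which(support, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 1L - margin, 0L)
  hi <- pmin(apply(idx, 2, max) - 1L + margin, shape - 1L)
  atlas <- list(
    prob = volume3d(prob, masks[[1]]$spacing, masks[[1]]$affine, "common"),
    support = binary_mask3d(support, masks[[1]]$spacing, masks[[1]]$affine,
                            "common"),
    crop_box = rbind(lo = as.integer(lo), hi = as.integer(hi)),
    margin = as.integer(margin))
  class(atlas) <- "prob_atlas"
  atlas
}

#' @export
print.prob_atlas <- function(x, ...) {
  cat(sprintf("<prob_atlas> %s grid, support %d voxels, crop box %s\n",
              paste(dim(x$prob$data), collapse = "x"), sum(x$support$data),
              paste(x$crop_box["hi", ] - x$crop_box["lo", ] + 1L,
                    collapse = "x")))
  invisible(x)
}

#' Sample patch centres from the atlas
#'
#' Centres are drawn (with replacement) from the atlas support with
#' probability proportional to the atlas value, concentrating patches where
#' the structure actually occurs.
#'
#' @param atlas [build_atlas()] result.
#' @param n number of centres (default 41, the per-subject training count).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return `n` x 3 integer matrix of 0-based voxel centres.
#' @export
sample_patch_centers <- function(atlas, n = 41L, seed = 1L) {
  if (n < 1) stopf("need at least one centre")
  pv <- atlas$prob$data
  idx <- which(pv > 0)
  if (!length(idx)) stopf("atlas support is empty")
  pick <- with_seed(seed, sample(length(idx), n, replace = TRUE,
                                 prob = pv[idx]))
  arrayInd(idx[pick], dim(pv)) - 1L
}

#' Extract a cubic patch around a voxel centre
#'
#' For even `size` the centre voxel occupies patch index `size/2` (0-based);
#' out-of-grid voxels are filled with `pad_value`.
#'
#' @param vol [volume3d()] or [binary_mask3d()], or a plain 3-D array.
#' @param center 0-based voxel coordinate, inside the grid.
#' @param size patch edge length in voxels (default 64).
#' @param pad_value fill value outside the grid.
#' @return `size`^3 array.
#' @export
extract_patch <- function(vol, center, size = 64L, pad_value = 0) {
  arr <- if (inherits(vol, "volume3d")) vol$data else vol
  shape <- dim(arr)
  center <- as.integer(round(center))
  if (any(center < 0L) || any(center > shape - 1L)) {
    stopf("patch centre (%s) outside grid %s", paste(center, collapse = ","),
          paste(shape, collapse = "x"))
  }
  size <- as.integer(size)
  # even size: centre sits at patch index size/2; odd: at (size-1)/2
  lo <- center - (size %/% 2L)
  hi <- lo + size - 1L
  patch <- array(pad_value, rep(size, 3))
  src_lo <- pmax(lo, 0L)
  src_hi <- pmin(hi, shape - 1L)
  if (all(src_lo <= src_hi)) {
    patch[(src_lo[1] - lo[1] + 1L):(src_hi[1] - lo[1] + 1L),
          (src_lo[2] - lo[2] + 1L):(src_hi[2] - lo[2] + 1L),
          (src_lo[3] - lo[3] + 1L):(src_hi[3] - lo[3] + 1L)] <-
      arr[(src_lo[1] + 1L):(src_hi[1] + 1L),
          (src_lo[2] + 1L):(src_hi[2] + 1L),
          (src_lo[3] + 1L):(src_hi[3] + 1L)]
  }
  patch
}

#' Mirror patches across the longitudinal fissure
#'
#' Flips along the left-right axis (axis 1 of the common-space grid), the
#' augmentation used during training. Image and label are flipped together
#' so they stay aligned.
#'
#' @param image 3-D array.
#' @param label optional 3-D array of the same shape.
#' @return `list(image, label)` with both mirrored (label `NULL` if absent).
#' @export
flip_lr <- function(image, label = NULL) {
  if (!is.null(label) && !identical(dim(image), dim(label))) {
    stopf("flip_lr: image and label shapes differ")
  }
  rev1 <- function(a) a[dim(a)[1]:1, , , drop = FALSE]
  list(image = rev1(image), label = if (is.null(label)) NULL else rev1(label))
}

#' Stitch overlapping score patches into a volume and binarise
#'
#' Each voxel's score is the arithmetic mean of all patch scores covering
#' it; voxels covered by no patch get -1 (the minimum of the tanh output
#' range). The mask keeps voxels with score strictly greater than
#' `threshold`.
#'
#' @param patches list of cubic score arrays (equal sizes).
#' @param centers matrix of 0-based voxel centres, one row per patch.
#' @param geometry target grid: a `volume3d` or `list(shape, spacing,
#'   affine)`.
#' @param threshold score threshold (default 0, i.e. probability 0.5 under
#'   the tanh-to-probability map).
#' @return `list(scores = volume3d, mask = binary_mask3d)`.
#' @export
stitch_and_binarize <- function(patches, centers, geometry, threshold = 0) {
  if (!length(patches)) stopf("stitch_and_binarize: empty patch list")
  centers <- matrix(as.integer(round(centers)), ncol = 3)
  if (nrow(centers) != length(patches)) {
    stopf("got %d patches but %d centres", length(patches), nrow(centers))
  }
  g <- geometry_of(geometry)
  size <- dim(patches[[1]])
  acc <- array(0, g$shape)
  cnt <- array(0L, g$shape)
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    if (!identical(dim(p), size)) stopf("patch %d has a different size", i)
    lo <- centers[i, ] - (size %/% 2L)
    hi <- lo + size - 1L
    src_lo <- pmax(lo, 0L)
    src_hi <- pmin(hi, g$shape - 1L)
    if (any(src_lo > src_hi)) next
    ti <- lapply(1:3, function(a) (src_lo[a] + 1L):(src_hi[a] + 1L))
    pi_ <- lapply(1:3, function(a) {
      (src_lo[a] - lo[a] + 1L):(src_hi[a] - lo[a] + 1L)
    })
    acc[ti[[1]], ti[[2]], ti[[3]]] <- acc[ti[[1]], ti[[2]], ti[[3]]] +
      p[pi_[[1]], pi_[[2]], pi_[[3]]]
    cnt[ti[[1]], ti[[2]], ti[[3]]] <- cnt[ti[[1]], ti[[2]], ti[[3]]] + 1L
  }
  covered <- cnt > 0L
  scores <- array(-1, g$shape)
  scores[covered] <- acc[covered] / cnt[covered]
  list(scores = volume3d(scores, g$spacing, g$affine, "common"),
       mask = binary_mask3d(scores > threshold, g$spacing, g$affine,
                            "common"))
}

#' Deterministic inference tiling of the atlas crop box
#'
#' Lays patch centres on a regular grid with the given stride so that the
#' union of patch footprints covers the whole crop box, clamping centres to
#' stay inside the grid.
#'
#' @param atlas [build_atlas()] result.
#' @param patch_size patch edge (voxels).
#' @param stride distance between neighbouring centres (defaults to half
#'   the patch size).
#' @return matrix of 0-based centres.
#' @export
tile_centers <- function(atlas, patch_size, stride = patch_size %/% 2L) {
  shape <- dim(atlas$prob$data)
  lo <- atlas$crop_box["lo", ]
  hi <- atlas$crop_box["hi", ]
  half <- patch_size %/% 2L
  axes <- lapply(1:3, function(a) {
    first <- lo[a] + half
    last <- hi[a] - (patch_size - half - 1L)
    cs <- if (last <= first) first else unique(c(seq(first, last, by = stride),
                                                 last))
    pmin(pmax(cs, 0L), shape[a] - 1L)
  })
  as.matrix(expand.grid(x = axes[[1]], y = axes[[2]], z = axes[[3]]))
}

#' Persist / load an atlas as NIfTI + JSON sidecar
#'
#' @param atlas `prob_atlas`.
#' @param path output path for the probability map (`.nii.gz`); the sidecar
#'   is written next to it with extension `.json`.
#' @return `write_atlas`: `path` invisibly; `read_atlas`: a `prob_atlas`.
#' @export
write_atlas <- function(atlas, path) {
  write_volume(atlas$prob, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(margin = atlas$margin,
                            crop_box = atlas$crop_box),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  prob <- read_volume(path, space = "common")
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- jsonlite::fromJSON(side)
  atlas <- list(prob = prob,
                support = binary_mask3d(prob$data > 0, prob$spacing,
                                        prob$affine, "common"),
                crop_box = matrix(as.integer(as.matrix(meta$crop_box)), 2, 3,
                                  dimnames = list(c("lo", "hi"), NULL)),
                margin = as.integer(meta$margin))
  class(atlas) <- "prob_atlas"
  atlas
}
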