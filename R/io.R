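# NIfTI input/output and grid resampling. All files go through RNifti;
# masks are written as unsigned 8-bit, images as float32.

#' Read a single 3-D NIfTI volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param mask logical; if `TRUE` the payload is binarised (any nonzero
#'   voxel becomes 1) and a [binary_mask3d()] is returned.
#' @param space space tag to attach, `"native"` by default.
#' @return A [volume3d()] or [binary_mask3d()].
#' @export
read_volume <- function(path, mask = FALSE, space = c("native", "common")) {
  space <- match.arg(space)
  if (!file.exists(path)) stopf("file does not exist: %s", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stopf("failed to read NIfTI '%s': %s",
                                            path, conditionMessage(e)))
  data <- as.array(img)
  if (length(dim(data)) == 4L && dim(data)[4] == 1L) {
    data <- array(data, dim(data)[1:3])
  }
  if (length(dim(data)) != 3L) {
    stopf("'%s' is %d-D; only single 3-D volumes are supported", path,
          length(dim(data)))
  }
  affine <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  affine <- matrix(as.numeric(affine), 4, 4)
  spacing <- as.numeric(RNifti::pixdim(img))[1:3]
  check_affine(affine)
  if (mask) {
    binary_mask3d(data, spacing = spacing, affine = affine, space = space)
  } else {
    volume3d(data, spacing = spacing, affine = affine, space = space)
  }
}

#' Write a volume or mask as NIfTI
#'
#' Masks are stored as uint8 in {0,1}; images as float32.
#'
#' @param v a [volume3d()] or [binary_mask3d()].
#' @param path output path (`.nii` or `.nii.gz`); the parent directory must
#'   exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  if (!inherits(v, "volume3d")) stopf("write_volume: not a volume3d")
  if (!dir.exists(dirname(path))) {
    stopf("parent directory does not exist: %s", dirname(path))
  }
  datatype <- if (is_mask(v)) "uint8" else "float"
  ni <- RNifti::asNifti(v$data)
  RNifti::pixdim(ni) <- v$spacing
  RNifti::sform(ni) <- structure(v$affine, code = 2L)
  RNifti::qform(ni) <- structure(v$affine, code = 2L)
  RNifti::writeNifti(ni, path, datatype = datatype)
  invisible(path)
}

#' Read / write a 4x4 transform as row-major text
#'
#' @param path text file with 16 whitespace-separated numbers (row-major).
#' @return `read_affine`: 4x4 matrix. `write_affine`: `path`, invisibly.
#' @export
read_affine <- function(path) {
  if (!file.exists(path)) stopf("transform file does not exist: %s", path)
  vals <- scan(path, quiet = TRUE)
  if (length(vals) != 16L) {
    stopf("transform file '%s' must hold 16 numbers, found %d", path,
          length(vals))
  }
  check_affine(matrix(vals, 4, 4, byrow = TRUE))
}

#' @rdname read_affine
#' @param m 4x4 matrix.
#' @export
write_affine <- function(m, path) {
  m <- check_affine(m)
  writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = " ")), path)
  invisible(path)
}

#' Resample a volume or mask under an affine world transform
#'
#' Pulls `src` onto `target_geometry` through `transform`, a 4x4 map from
#' source world coordinates (mm) to target world coordinates. Out-of-field
#' voxels are filled with 0. Masks must be resampled with nearest-neighbour
#' interpolation so no fractional labels can appear.
#'
#' @param src [volume3d()] or [binary_mask3d()].
#' @param transform 4x4 source-world to target-world map (e.g. a rigid
#'   common-to-native transform). Use `diag(4)` for a pure regridding.
#' @param target_geometry a `volume3d` or `list(shape, spacing, affine)`.
#' @param interp `"trilinear"` or `"nearest"`. Masks require `"nearest"`.
#' @param space space tag for the output.
#' @return Same kind of object as `src`, on the target grid.
#' @export
resample_with_affine <- function(src, transform, target_geometry,
                                 interp = c("trilinear", "nearest"),
                                 space = src$space) {
  interp <- match.arg(interp)
  if (is_mask(src) && interp != "nearest") {
    stopf("masks must be resampled with nearest-neighbour interpolation")
  }
  transform <- check_affine(transform)
  tg <- geometry_of(target_geometry)
  # target voxel index -> source voxel index (both 0-based)
  M <- solve(src$affine) %*% solve(transform) %*% tg$affine
  out <- resample_affine_cpp(as.numeric(src$data), as.integer(dim(src$data)),
                             M, as.integer(tg$shape),
                             nearest = (interp == "nearest"))
  out <- array(out, tg$shape)
  if (is_mask(src)) {
    binary_mask3d(out, spacing = tg$spacing, affine = tg$affine, space = space)
  } else {
    volume3d(out, spacing = tg$spacing, affine = tg$affine, space = space)
  }
}
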