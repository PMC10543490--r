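# Carriers for 3-D image data. A volume3d couples a numeric 3-D grid with
# voxel spacing (mm), a 4x4 grid-to-world affine in the NIfTI convention
# (0-based voxel index -> mm), and a space tag ("common" or "native").
# binary_mask3d shares the geometry and restricts values to {0, 1}.

#' Construct a 3-D volume
#'
#' @param data numeric 3-D array.
#' @param spacing voxel spacing in mm, length 3, strictly positive.
#' @param affine 4x4 grid-index-to-world-mm map (0-based indices, NIfTI
#'   convention). Defaults to an axis-aligned grid centred on the world
#'   origin.
#' @param space `"common"` (template space) or `"native"` (subject space).
#' @return An object of class `volume3d` with fields `data`, `spacing`,
#'   `affine` and `space`.
#' @examples
#' v <- volume3d(array(0, c(8, 8, 8)), spacing = c(1, 1, 1))
#' v$spacing
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), affine = NULL,
                     space = c("common", "native")) {
  space <- match.arg(space)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stopf("volume3d: `data` must be a 3-D array, got %s dimension(s)",
          length(dim(data)) %||% "no")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stopf("volume3d: spacing must be 3 strictly positive numbers")
  }
  if (is.null(affine)) affine <- centered_affine(dim(data), spacing)
  affine <- check_affine(affine)
  structure(list(data = data, spacing = spacing, affine = affine,
                 space = space),
            class = "volume3d")
}

#' Construct a binary 3-D mask
#'
#' Any nonzero voxel is treated as foreground (tolerant of 255-coded masks).
#'
#' @inheritParams volume3d
#' @param data 3-D array; coerced to integer 0/1.
#' @return An object of class `binary_mask3d` (also inheriting `volume3d`).
#' @export
binary_mask3d <- function(data, spacing = c(1, 1, 1), affine = NULL,
                          space = c("common", "native")) {
  space <- match.arg(space)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stopf("binary_mask3d: `data` must be a 3-D array")
  }
  d <- array(as.integer(data != 0), dim(data))
  v <- volume3d(d, spacing = spacing, affine = affine, space = space)
  class(v) <- c("binary_mask3d", "volume3d")
  v
}

is_mask <- function(x) inherits(x, "binary_mask3d")

#' @export
print.volume3d <- function(x, ...) {
  kind <- if (is_mask(x)) "binary_mask3d" else "volume3d"
  cat(sprintf("<%s> %s voxels, spacing %s mm, %s space\n", kind,
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"), x$space))
  if (is_mask(x)) {
    cat(sprintf("  foreground voxels: %d (%.3f cm^3)\n", sum(x$data),
                mask_volume_cm3(x)))
  } else {
    cat(sprintf("  intensity range: [%.4g, %.4g]\n", min(x$data), max(x$data)))
  }
  invisible(x)
}

#' Axis-aligned affine centring the grid on the world origin
#' @keywords internal
centered_affine <- function(shape, spacing) {
  a <- diag(4)
  diag(a)[1:3] <- spacing
  a[1:3, 4] <- -(shape - 1) / 2 * spacing
  a
}

check_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || any(!is.finite(affine))) {
    stopf("affine must be a finite 4x4 matrix")
  }
  d <- det(affine[1:3, 1:3])
  if (!is.finite(d) || abs(d) < 1e-12) {
    stopf("affine is not invertible (det = %g)", d)
  }
  affine
}

#' Geometry descriptor of a volume or mask
#'
#' @param x a `volume3d`/`binary_mask3d`, or a list with fields `shape`,
#'   `spacing`, `affine` (passed through after validation).
#' @return list with `shape`, `spacing`, `affine`.
#' @export
geometry_of <- function(x) {
  if (inherits(x, "volume3d")) {
    return(list(shape = dim(x$data), spacing = x$spacing, affine = x$affine))
  }
  if (is.list(x) && all(c("shape", "spacing", "affine") %in% names(x))) {
    return(list(shape = as.integer(x$shape), spacing = as.numeric(x$spacing),
                affine = check_affine(x$affine)))
  }
  stopf("cannot interpret target geometry; give a volume or a %s",
        "list(shape, spacing, affine)")
}

same_geometry <- function(a, b, tol = 1e-6) {
  ga <- geometry_of(a)
  gb <- geometry_of(b)
  all(ga$shape == gb$shape) &&
    max(abs(ga$spacing - gb$spacing)) < tol &&
    max(abs(ga$affine - gb$affine)) < tol
}

stopifnot_same_geometry <- function(a, b, what = "inputs") {
  if (!same_geometry(a, b)) stopf("%s do not share grid geometry", what)
  invisible(TRUE)
}
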