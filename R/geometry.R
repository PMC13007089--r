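#' Voxel grid geometry
#'
#' A `grid_geometry` couples the voxel grid shape with the physical voxel
#' spacing (mm) and a 4x4 world affine. All metric computations in the
#' package (distances, areas, patch sizes) use the spacing; the affine is
#' carried through so derived volumes can be written back in register with
#' their inputs.
#'
#' @param shape Integer triple, voxels per axis (each >= 1).
#' @param spacing Positive numeric triple, mm per voxel along each axis.
#' @param affine Optional 4x4 world transform (mm). Defaults to a diagonal
#'   affine built from `spacing` with the origin at voxel (1,1,1). If
#'   supplied, its column norms must agree with `spacing` to within 1e-6 mm.
#' @return An object of class `grid_geometry` with fields `shape`,
#'   `spacing` and `affine`.
#' @examples
#' grid_geometry(c(64, 64, 32), c(3, 3, 3))
#' @export
grid_geometry <- function(shape, spacing, affine = NULL) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (length(shape) != 3 || any(is.na(shape)) || any(shape < 1)) {
    abort("`shape` must be an integer triple with all entries >= 1")
  }
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    bad <- which(!is.finite(spacing) | spacing <= 0)[1]
    abort(sprintf("`spacing` must be a positive finite triple; axis %d is invalid", bad))
  }
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4))) abort("`affine` must be a 4x4 matrix")
  sp_aff <- spacing_from_affine(affine)
  if (any(abs(sp_aff - spacing) > 1e-6)) {
    abort(sprintf(
      "affine column norms (%s) disagree with spacing (%s) beyond 1e-6 mm",
      paste(signif(sp_aff, 8), collapse = ", "),
      paste(signif(spacing, 8), collapse = ", ")))
  }
  structure(list(shape = shape, spacing = spacing, affine = affine),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %s voxels @ %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' Recover voxel spacing from an affine
#'
#' @param affine 4x4 world transform.
#' @return Numeric triple of column norms of the 3x3 rotation/scale block.
#' @export
spacing_from_affine <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' Check two grids describe the same voxel lattice
#'
#' Shapes must be identical and affines equal entrywise within `tol`.
#'
#' @param a,b `grid_geometry` objects.
#' @param tol Absolute tolerance on affine entries (mm).
#' @return `TRUE` invisibly, or an error naming the mismatch.
#' @export
check_grid_compatible <- function(a, b, tol = 1e-4) {
  if (!identical(as.integer(a$shape), as.integer(b$shape))) {
    abort(sprintf("grid shapes differ: %s vs %s",
                  paste(a$shape, collapse = "x"),
                  paste(b$shape, collapse = "x")))
  }
  if (max(abs(a$affine - b$affine)) > tol) {
    abort(sprintf("grid affines differ by up to %.3g (> %g tolerance)",
                  max(abs(a$affine - b$affine)), tol))
  }
  invisible(TRUE)
}

# world coordinates (mm) of 1-based voxel indices under a geometry
voxel_to_world <- function(idx, geometry) {
  idx0 <- sweep(as.matrix(idx), 2, c(1, 1, 1)) # affine maps 0-based indices
  t(geometry$affine %*% t(cbind(idx0, 1)))[, 1:3, drop = FALSE]
}

# 1-based (fractional) voxel indices of world coordinates (mm)
world_to_voxel <- function(xyz, geometry) {
  inv <- solve(geometry$affine)
  t(inv %*% t(cbind(as.matrix(xyz), 1)))[, 1:3, drop = FALSE] + 1
}
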