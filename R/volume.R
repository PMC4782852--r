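#' Construct a volume grid
#'
#' A `volume_grid` holds a 3D scalar array (binary lumen mask, anti-aliased
#' occupancy, or CT attenuation) together with its geometry: per-axis voxel
#' spacing in mm and the 4x4 affine mapping 0-based voxel indices to world
#' coordinates in mm (NIfTI RAS convention).
#'
#' @param voxels 3D numeric or logical array.
#' @param spacing per-axis voxel size in mm (length 3, all > 0). Ignored if
#'   `affine` is given (spacing is then derived from the affine columns).
#' @param affine 4x4 voxel-to-world matrix; defaults to `diag(spacing)` with
#'   the origin at voxel (0, 0, 0).
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(voxels, spacing = c(1, 1, 1), affine = NULL) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (is.null(affine)) {
    spacing <- as.numeric(spacing)
    if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
      stop("spacing must be 3 positive values in mm")
    affine <- diag(c(spacing, 1))
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L))) stop("affine must be a 4x4 matrix")
    if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
    spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  structure(list(voxels = voxels, spacing = spacing, affine = affine),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels, spacing %s mm, values in [%.3g, %.3g]\n",
              paste(dim(x$voxels), collapse = " x "),
              paste(signif(x$spacing, 4), collapse = " x "),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @rdname volume_grid
#' @param x object to test.
#' @export
is_volume_grid <- function(x) inherits(x, "volume_grid")

# world mm -> continuous 0-based voxel index; pts is n x 3
world_to_voxel <- function(volume, pts) {
  pts <- rbind(t(as.matrix(pts)), 1)
  idx <- solve(volume$affine, pts)
  t(idx[1:3, , drop = FALSE])
}

# continuous 0-based voxel index -> world mm; idx is n x 3
voxel_to_world <- function(volume, idx) {
  idx <- rbind(t(as.matrix(idx)), 1)
  t((volume$affine %*% idx)[1:3, , drop = FALSE])
}

# Interpolate the volume at world points (n x 3); points outside the grid
# return `outside`. "cubic" is separable Catmull-Rom convolution, "linear"
# is trilinear.
interp_volume <- function(volume, pts, method = c("cubic", "linear"), outside = 0) {
  method <- match.arg(method)
  g <- world_to_voxel(volume, pts)             # 0-based continuous
  .interp3(as.numeric(volume$voxels), as.integer(dim(volume$voxels)),
           g, if (method == "cubic") 3L else 1L, outside)
}
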