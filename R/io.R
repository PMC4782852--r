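#' Read a volume from NIfTI
#'
#' Loads a `.nii` / `.nii.gz` volume, taking the voxel-to-world affine (mm)
#' from the sform/qform header, into a [volume_grid()].
#'
#' @param path NIfTI file path.
#' @return a [volume_grid()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  volume_grid(array(as.numeric(img), dim = dim(img)), affine = unclass(aff)[1:4, 1:4])
}

#' Write a volume to NIfTI
#'
#' @param volume a [volume_grid()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(is_volume_grid(volume))
  img <- RNifti::asNifti(volume$voxels)
  img <- RNifti::`sform<-`(img, structure(volume$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(volume$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read seed and landmark points from a JSON file
#'
#' Expected keys: `seed_proximal`, `seed_distal` (world mm, length-3 arrays)
#' and optionally `landmark_proximal`, `landmark_distal` (defaulting to the
#' seeds).
#'
#' @param path JSON file path.
#' @return named list of numeric length-3 world points.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("seed_proximal", "seed_distal")
  if (!all(need %in% names(j)))
    stop("landmarks JSON needs 'seed_proximal' and 'seed_distal'")
  for (k in intersect(c(need, "landmark_proximal", "landmark_distal"), names(j)))
    if (length(j[[k]]) != 3L || !is.numeric(j[[k]]))
      stop(sprintf("'%s' must be a numeric [x, y, z] triple in mm", k))
  j[intersect(c(need, "landmark_proximal", "landmark_distal"), names(j))]
}

#' Threshold a contrast-enhanced CT volume into a lumen mask
#'
#' Binary mask of voxels at or above an attenuation threshold (contrast-filled
#' lumen is bright); when a seed is given, only the connected component
#' containing it is retained, which drops other opacified structures.
#'
#' @param ct a [volume_grid()] of attenuation-like values (e.g. HU).
#' @param hu_threshold attenuation threshold (default 200 HU).
#' @param seed optional world point (mm) inside the lumen.
#' @return a binary [volume_grid()] with the same geometry.
#' @export
threshold_lumen <- function(ct, hu_threshold = 200, seed = NULL) {
  stopifnot(is_volume_grid(ct))
  fg <- ct$voxels >= hu_threshold
  if (!any(fg)) stop(sprintf("no voxels at or above %g: empty lumen mask", hu_threshold))
  if (!is.null(seed)) {
    dm <- dim(ct$voxels)
    v <- round(world_to_voxel(ct, rbind(as.numeric(seed))))
    if (any(v < 0) || any(v > dm - 1L)) stop("seed is outside the volume")
    lin0 <- as.integer(v[1L] + dm[1L] * (v[2L] + dm[2L] * v[3L]))
    if (!fg[lin0 + 1L]) stop("seed voxel is below the threshold")
    keep <- .component_mask(as.logical(fg), as.integer(dm), lin0)
    fg <- array(keep, dim = dm)
  }
  volume_grid(array(as.numeric(fg), dim = dim(ct$voxels)), affine = ct$affine)
}
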