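#' Build cross-section plane frames along a centerline
#'
#' One orthonormal frame per centerline point: the plane normal is the local
#' tangent, and the in-plane axes (u, v) are propagated along the curve by
#' parallel transport (rotation-minimizing frames), so consecutive slices do
#' not spin arbitrarily about the centerline.
#'
#' @param cl a [centerline()], normally regularized with
#'   [smooth_and_resample()] first.
#' @return an object of class `plane_frames`: list with n x 3 matrices
#'   `origin`, `normal`, `u`, `v` and the arc length vector `s`. Each triad
#'   `{u, v, normal}` is right-handed orthonormal.
#' @export
plane_frames <- function(cl) {
  stopifnot(inherits(cl, "centerline"))
  tg <- cl$tangents
  n <- nrow(tg)
  u <- matrix(0, n, 3L)
  v <- matrix(0, n, 3L)
  # initial u: world axis least aligned with the first tangent, projected
  ax <- diag(3L)[, which.min(abs(tg[1L, ])), drop = TRUE]
  u0 <- ax - sum(ax * tg[1L, ]) * tg[1L, ]
  u[1L, ] <- u0 / sqrt(sum(u0^2))
  v[1L, ] <- cross3(tg[1L, ], u[1L, ])
  for (i in seq_len(n - 1L)) {
    # project previous u off the new tangent (first-order parallel transport)
    w <- u[i, ] - sum(u[i, ] * tg[i + 1L, ]) * tg[i + 1L, ]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-9) stop("degenerate frame transport: tangent flipped by ~90 degrees between consecutive points")
    u[i + 1L, ] <- w / nw
    v[i + 1L, ] <- cross3(tg[i + 1L, ], u[i + 1L, ])
  }
  structure(list(origin = cl$points, normal = tg, u = u, v = v, s = cl$arclength),
            class = "plane_frames")
}

#' @export
print.plane_frames <- function(x, ...) {
  cat(sprintf("<plane_frames> %d frames over %.2f mm\n", nrow(x$origin), max(x$s)))
  invisible(x)
}

#' @rdname plane_frames
#' @param frames a `plane_frames` object.
#' @param i frame index.
#' @return `frame_at()` returns a single frame: list with `origin`, `normal`,
#'   `u`, `v` (3-vectors) and arc length `s`.
#' @export
frame_at <- function(frames, i) {
  list(origin = frames$origin[i, ], normal = frames$normal[i, ],
       u = frames$u[i, ], v = frames$v[i, ], s = frames$s[i])
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Resample the volume on a cross-section plane
#'
#' Multiplanar reconstruction of one slice: a square in-plane grid centered
#' at the frame origin is mapped to world coordinates through the frame axes
#' and the volume is sampled there by trilinear interpolation. Samples outside
#' the volume are background (0).
#'
#' @param volume a [volume_grid()].
#' @param frame a single frame from [frame_at()].
#' @param half_extent_mm half the side length of the sampled square (mm);
#'   must cover the expected lumen radius (default 40, ample for any aorta).
#' @param grid_spacing_mm in-plane sample spacing (mm, default 0.5).
#' @param interpolation `"cubic"` (separable Catmull-Rom, the default: its
#'   flat pass-band preserves wall undulations a few voxels across that
#'   trilinear interpolation measurably attenuates) or `"linear"`.
#' @return an object of class `mpr_image`: list with in-plane coordinate
#'   vectors `x`, `y` (mm, zero at the centerline point) and the sample
#'   matrix `values` (length(x) by length(y)).
#' @export
sample_plane <- function(volume, frame, half_extent_mm = 40, grid_spacing_mm = 0.5,
                         interpolation = c("cubic", "linear")) {
  stopifnot(is_volume_grid(volume))
  if (grid_spacing_mm <= 0) stop("grid_spacing_mm must be > 0")
  if (half_extent_mm <= 0) stop("half_extent_mm must be > 0")
  g <- seq(-half_extent_mm, half_extent_mm, by = grid_spacing_mm)
  xy <- cbind(rep(g, times = length(g)), rep(g, each = length(g)))
  pts <- rep(frame$origin, each = nrow(xy)) +
    outer(xy[, 1L], frame$u) + outer(xy[, 2L], frame$v)
  vals <- interp_volume(volume, pts, method = match.arg(interpolation), outside = 0)
  structure(list(x = g, y = g,
                 values = matrix(vals, nrow = length(g), ncol = length(g))),
            class = "mpr_image")
}

#' @export
print.mpr_image <- function(x, ...) {
  cat(sprintf("<mpr_image> %d x %d samples, extent %.1f mm\n",
              length(x$x), length(x$y), diff(range(x$x))))
  invisible(x)
}

#' Trace the luminal contour on a cross-section image
#'
#' Sub-pixel iso-contour extraction (marching squares with linear
#' interpolation, via [grDevices::contourLines()]) at the stated level. Among
#' all closed iso-contours, the one enclosing `center_mm` — the centerline
#' point — is returned, oriented counter-clockwise and resampled to a fixed
#' vertex count.
#'
#' @param plane_image an `mpr_image` from [sample_plane()].
#' @param center_mm in-plane point the contour must enclose (default the
#'   centerline point, i.e. the in-plane origin).
#' @param level iso-level: 0.5 traces the half-occupancy boundary of a binary
#'   or anti-aliased mask.
#' @param n_vertices vertex count of the returned contour (default 720).
#' @return a [contour()]. If no closed contour encloses the center an error
#'   of class `shag_no_contour` is signalled (the scoring loop catches it and
#'   flags the slice instead of aborting).
#' @export
extract_lumen_contour <- function(plane_image, center_mm = c(0, 0), level = 0.5,
                                  n_vertices = 720L) {
  stopifnot(inherits(plane_image, "mpr_image"))
  rng <- range(plane_image$values)
  fail <- function(msg) stop(errorCondition(msg, class = c("shag_no_contour", "shag_error")))
  if (rng[1L] >= level || rng[2L] <= level)
    fail(sprintf("no iso-contour at level %g: image values span [%.3g, %.3g]",
                 level, rng[1L], rng[2L]))
  # samples exactly equal to the level (common with strictly binary masks)
  # make marching squares emit broken open fragments; a tiny deterministic
  # offset breaks the ties without measurably moving the contour
  if (any(plane_image$values == level))
    level <- level + 1e-7 * (rng[2L] - rng[1L])
  cls <- grDevices::contourLines(plane_image$x, plane_image$y,
                                 plane_image$values, levels = level)
  for (cl in cls) {
    p <- cbind(cl$x, cl$y)
    closed <- all(abs(p[nrow(p), ] - p[1L, ]) < 1e-9)
    if (!closed || nrow(p) < 4L) next
    p <- p[-nrow(p), , drop = FALSE]
    if (point_in_polygon(center_mm, p))
      return(resample_contour(contour(p), n_vertices))
  }
  fail(sprintf("no closed iso-contour encloses the center point (%.1f, %.1f) mm",
               center_mm[1L], center_mm[2L]))
}
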