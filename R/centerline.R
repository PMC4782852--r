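#' Construct a centerline
#'
#' An ordered 3D polyline through the vessel lumen, with cumulative arc length
#' and unit tangents. Usually produced by [extract_centerline()] and
#' regularized with [smooth_and_resample()] rather than built directly.
#'
#' @param points n x 3 matrix of world coordinates in mm (n >= 2), ordered
#'   proximal to distal, with no repeated consecutive points.
#' @return an object of class `centerline` with fields `points`, `arclength`
#'   (mm, starting at 0, strictly increasing) and `tangents` (unit vectors,
#'   central differences).
#' @export
centerline <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 2L)
    stop("centerline points must be an n x 3 matrix with n >= 2")
  step <- sqrt(rowSums(diff(points)^2))
  if (any(step <= 0)) stop("centerline has repeated consecutive points")
  structure(list(points = points,
                 arclength = c(0, cumsum(step)),
                 tangents = polyline_tangents(points)),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, length %.2f mm\n",
              nrow(x$points), max(x$arclength)))
  invisible(x)
}

# unit tangents by central differences (one-sided at the ends)
polyline_tangents <- function(points) {
  n <- nrow(points)
  tg <- matrix(0, n, 3L)
  tg[1L, ] <- points[2L, ] - points[1L, ]
  tg[n, ] <- points[n, ] - points[n - 1L, ]
  if (n > 2L) tg[2:(n - 1L), ] <- points[3:n, , drop = FALSE] - points[1:(n - 2L), , drop = FALSE]
  nrm <- sqrt(rowSums(tg^2))
  if (any(nrm < 1e-12)) stop("degenerate (zero) tangent on centerline")
  tg / nrm
}

#' Extract the central luminal line from a binary mask
#'
#' Finds a path between two user-supplied seed points that stays inside the
#' lumen and hugs the medial axis: a minimum-cost path on the 26-connected
#' foreground voxel graph, where the cost of a step of length `ds` between
#' voxels `a` and `b` is `ds * (c(a) + c(b)) / 2` with medialness weight
#' `c(v) = 1 / (1 + DT(v))^2` and `DT` the Euclidean distance (mm) to the
#' lumen boundary. Large distance-to-boundary voxels are therefore strongly
#' preferred, which pulls the path to the locus of maximal inscribed spheres.
#'
#' The raw voxel path should normally be regularized with
#' [smooth_and_resample()] before building cross-section planes.
#'
#' @param mask a [volume_grid()]; voxels with value >= 0.5 are foreground.
#' @param seed_proximal,seed_distal world coordinates (mm) of the two ends of
#'   the segment; both must fall in foreground and be connected through it.
#' @return a [centerline()] from the proximal to the distal seed.
#' @export
extract_centerline <- function(mask, seed_proximal, seed_distal) {
  stopifnot(is_volume_grid(mask))
  fg <- as.logical(mask$voxels >= 0.5)
  if (!any(fg)) stop("empty mask: no foreground voxels")
  dm <- dim(mask$voxels)

  seed_idx <- function(pt, label) {
    v <- round(world_to_voxel(mask, rbind(pt)))
    if (any(v < 0) || any(v > dm - 1L))
      stop(sprintf("%s seed is outside the volume", label))
    lin <- 1L + v[1L] + dm[1L] * (v[2L] + dm[2L] * v[3L])
    if (!fg[lin])
      stop(sprintf("%s seed at (%.1f, %.1f, %.1f) mm is not inside the lumen mask",
                   label, pt[1L], pt[2L], pt[3L]))
    as.integer(lin - 1L)
  }
  s0 <- seed_idx(as.numeric(seed_proximal), "proximal")
  s1 <- seed_idx(as.numeric(seed_distal), "distal")

  dt <- .edt_3d(fg, as.integer(dm), mask$spacing)
  path <- .dijkstra_medial_path(fg, dt, as.integer(dm), mask$spacing, s0, s1)
  if (length(path) == 0L) {
    n0 <- .component_size(fg, as.integer(dm), s0)
    n1 <- .component_size(fg, as.integer(dm), s1)
    stop(sprintf(paste0("seeds lie in disconnected lumen components ",
                        "(proximal component: %d voxels, distal component: %d voxels)"),
         n0, n1))
  }
  idx0 <- path                                   # 0-based linear
  k <- idx0 %/% (dm[1L] * dm[2L])
  rem <- idx0 %% (dm[1L] * dm[2L])
  vox <- cbind(rem %% dm[1L], rem %/% dm[1L], k)
  centerline(voxel_to_world(mask, vox))
}

#' Smooth and regularly resample a centerline
#'
#' Applies moving-average smoothing (to suppress voxel-scale zig-zag that
#' would corrupt the perpendicular-plane normals) and then resamples the
#' polyline at a regular arc-length spacing — the cross-sectional slice
#' thickness of the score, conventionally 1.2 to 1.7 mm.
#'
#' @param cl a [centerline()].
#' @param spacing_mm target arc-length spacing in mm (default 1.5, the
#'   midpoint of the conventional 1.2-1.7 mm range). Values outside
#'   `[0.5, 5]` trigger a warning.
#' @param smooth_window_mm moving-average window in mm (default 10; 0
#'   disables smoothing). The window shrinks symmetrically near the ends so
#'   endpoints stay anchored.
#' @return a [centerline()] with points equally spaced at `spacing_mm` and
#'   tangents recomputed by central differences.
#' @export
smooth_and_resample <- function(cl, spacing_mm = 1.5, smooth_window_mm = 10) {
  stopifnot(inherits(cl, "centerline"))
  if (!is.numeric(spacing_mm) || spacing_mm <= 0) stop("spacing_mm must be > 0")
  if (spacing_mm < 0.5 || spacing_mm > 5)
    warning(sprintf("slice spacing %.2f mm is outside the conventional 0.5-5 mm range", spacing_mm))
  p <- cl$points
  s <- cl$arclength
  if (smooth_window_mm > 0 && nrow(p) > 2L) {
    half <- smooth_window_mm / 2
    sm <- p
    for (i in seq_len(nrow(p))) {
      # symmetric window, shrunk near the ends so the mean stays centered
      h <- min(half, s[i] - s[1L], s[length(s)] - s[i])
      if (h <= 0) next
      w <- which(s >= s[i] - h & s <= s[i] + h)
      sm[i, ] <- colMeans(p[w, , drop = FALSE])
    }
    p <- sm
    # smoothing can merge consecutive points; drop duplicates
    keep <- c(TRUE, sqrt(rowSums(diff(p)^2)) > 1e-9)
    p <- p[keep, , drop = FALSE]
    s <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  }
  total <- s[length(s)]
  if (spacing_mm > total)
    stop(sprintf("spacing %.2f mm exceeds centerline length %.2f mm", spacing_mm, total))
  target <- seq(0, total, by = spacing_mm)
  out <- vapply(1:3, function(d) stats::approx(s, p[, d], xout = target)$y,
                numeric(length(target)))
  centerline(out)
}

#' Refine a centerline to sub-voxel accuracy
#'
#' A minimum-cost path on the voxel graph can only pass through voxel
#' centers, so even after smoothing the extracted line may sit a constant
#' fraction of a voxel off the true luminal center — enough to bias the mean
#' through-center diameter. This stage re-centers each point in its own
#' perpendicular plane: the luminal contour is traced there and the point is
#' moved to the contour's area centroid, then the line is re-smoothed and
#' resampled at its original spacing. One or two iterations bring a straight
#' tube's line to within a few hundredths of a voxel of the true axis.
#'
#' @param volume the lumen [volume_grid()] the line was extracted from.
#' @param cl a regular [centerline()] (from [smooth_and_resample()]).
#' @param iterations re-centering passes (default 2).
#' @param half_extent_mm,grid_spacing_mm,level,interpolation contour tracing
#'   parameters as in [sample_plane()] / [extract_lumen_contour()].
#' @param smooth_window_mm re-smoothing window between passes (default 10).
#' @return a refined [centerline()] with the same point spacing. Points whose
#'   plane yields no enclosing contour (e.g. beyond the lumen ends) are left
#'   where they were.
#' @export
refine_centerline <- function(volume, cl, iterations = 2L,
                              half_extent_mm = 40, grid_spacing_mm = 0.5,
                              level = 0.5, interpolation = "cubic",
                              smooth_window_mm = 10) {
  stopifnot(inherits(cl, "centerline"))
  spacing <- stats::median(diff(cl$arclength))
  for (it in seq_len(iterations)) {
    fr <- plane_frames(cl)
    pts <- cl$points
    for (i in seq_len(nrow(pts))) {
      f <- frame_at(fr, i)
      ct <- tryCatch({
        img <- sample_plane(volume, f, half_extent_mm, grid_spacing_mm,
                            interpolation = interpolation)
        extract_lumen_contour(img, center_mm = c(0, 0), level = level,
                              n_vertices = 180L)
      }, shag_no_contour = function(e) NULL)
      if (is.null(ct)) next
      cen <- contour_centroid(ct)
      pts[i, ] <- f$origin + cen[1L] * f$u + cen[2L] * f$v
    }
    cl <- smooth_and_resample(centerline(pts), spacing_mm = spacing,
                              smooth_window_mm = smooth_window_mm)
  }
  cl
}
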