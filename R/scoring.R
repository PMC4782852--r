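#' Measurement settings for slice metrology
#'
#' Collects every knob that affects a per-slice measurement, with the
#' conventional defaults: 180 diameter measurements per slice, 720 contour
#' vertices, a 0.5 iso-level for (anti-aliased) binary masks, and an in-plane
#' grid of 0.5 mm covering +/- 40 mm.
#'
#' @param half_extent_mm in-plane half extent of the resampled slice (mm).
#' @param grid_spacing_mm in-plane sample spacing (mm).
#' @param level iso-level of the luminal boundary.
#' @param n_vertices contour vertex count after resampling.
#' @param n_angles number of through-center diameters per slice.
#' @param crossing ray-crossing policy for non-convex contours; see
#'   [diameter_fan()].
#' @param pi_value value of pi in the circularity ratio; see
#'   [circularity_ratio()].
#' @param interpolation volume interpolation for plane resampling; see
#'   [sample_plane()].
#' @return a named list of class `measure_settings`.
#' @export
measure_settings <- function(half_extent_mm = 40, grid_spacing_mm = 0.5,
                             level = 0.5, n_vertices = 720L, n_angles = 180L,
                             crossing = "first", pi_value = pi,
                             interpolation = "cubic") {
  structure(list(half_extent_mm = half_extent_mm,
                 grid_spacing_mm = grid_spacing_mm,
                 level = level, n_vertices = as.integer(n_vertices),
                 n_angles = as.integer(n_angles),
                 crossing = crossing, pi_value = pi_value,
                 interpolation = interpolation),
            class = "measure_settings")
}

#' Measure one cross-section slice
#'
#' Runs the full per-slice chain: resample the volume on the plane, trace the
#' luminal contour, measure its length `A` and the 180-angle mean diameter
#' `B` through the centerline point, and form `C = A / (pi B)` and the
#' irregularity `(C - 1) * 100`. Failures never abort: a slice with no
#' enclosing contour is returned with the `no_contour` flag and `NA`
#' measurements, and a centerline point falling outside the traced contour
#' (crescent or strongly eccentric lumen) triggers a centroid fallback with
#' the `centroid_fallback` flag.
#'
#' @param volume a [volume_grid()].
#' @param frame a single plane frame from [frame_at()].
#' @param s arc length (mm) of this slice along the centerline.
#' @param settings a [measure_settings()] list.
#' @return one-row tibble with columns `s_mm`, `A_mm`, `B_mm`, `C`,
#'   `irregularity`, `flags` (";"-joined, empty when clean).
#' @export
measure_slice <- function(volume, frame, s, settings = measure_settings()) {
  flags <- character(0)
  row <- function(A, B, C) {
    tibble::tibble(s_mm = s, A_mm = A, B_mm = B, C = C,
                   irregularity = if (is.na(C)) NA_real_ else slice_irregularity(C),
                   flags = paste(flags, collapse = ";"))
  }
  img <- sample_plane(volume, frame, settings$half_extent_mm, settings$grid_spacing_mm,
                      interpolation = settings$interpolation)
  ct <- tryCatch(
    extract_lumen_contour(img, center_mm = c(0, 0), level = settings$level,
                          n_vertices = settings$n_vertices),
    shag_no_contour = function(e) NULL)
  if (is.null(ct)) {
    flags <- "no_contour"
    return(row(NA_real_, NA_real_, NA_real_))
  }
  A <- perimeter(ct)
  fan <- tryCatch(
    tryCatch(
      diameter_fan(ct, center = c(0, 0), n_angles = settings$n_angles,
                   crossing = settings$crossing),
      shag_center_outside = function(e) {
        flags <<- c(flags, "centroid_fallback")
        diameter_fan(ct, center = contour_centroid(ct),
                     n_angles = settings$n_angles, crossing = settings$crossing)
      }),
    shag_error = function(e) {
      flags <<- c(flags, "fan_failed")
      NULL
    })
  if (is.null(fan)) return(row(A, NA_real_, NA_real_))
  C <- circularity_ratio(A, fan$mean_diameter, pi_value = settings$pi_value)
  row(A, fan$mean_diameter, C)
}

#' Measure every slice along a set of plane frames
#'
#' @param volume a [volume_grid()].
#' @param frames a [plane_frames()] object.
#' @param settings a [measure_settings()] list.
#' @return tibble with one row per frame (columns as in [measure_slice()]),
#'   with the settings attached as attribute `"settings"`.
#' @export
measure_slices <- function(volume, frames, settings = measure_settings()) {
  stopifnot(inherits(frames, "plane_frames"))
  out <- purrr::map_dfr(seq_len(nrow(frames$origin)), function(i)
    measure_slice(volume, frame_at(frames, i), s = frames$s[i], settings = settings))
  attr(out, "settings") <- settings
  out
}

#' Aggregate per-slice measurements into the shagginess score
#'
#' The score is the unweighted arithmetic mean of the per-slice irregularity
#' `(C - 1) * 100` over all slices whose arc length lies in
#' `[s_prox, s_dist]` (inclusive) and that carry no failure or exclusion
#' flag. Flagged slices are excluded from the mean but kept in the per-slice
#' table so the exclusion is auditable.
#'
#' @param measurements tibble from [measure_slices()] (or any tibble with
#'   columns `s_mm`, `irregularity`, `flags`).
#' @param s_prox,s_dist arc-length range (mm) of the scored segment, normally
#'   from [landmarks_to_arclength()]; `s_prox < s_dist`.
#' @param settings optional [measure_settings()] to record; defaults to the
#'   `"settings"` attribute of `measurements`.
#' @return an object of class `shagginess_result`: list with `score`,
#'   `n_slices_used`, `s_range`, `slices` (the full per-slice tibble with an
#'   added logical `used` column) and `settings`.
#' @export
shagginess_score <- function(measurements, s_prox, s_dist, settings = NULL) {
  if (!is.numeric(s_prox) || !is.numeric(s_dist) || !(s_prox < s_dist))
    stop("s_prox must be less than s_dist")
  if (is.null(settings)) settings <- attr(measurements, "settings")
  m <- tibble::as_tibble(measurements)
  in_range <- m$s_mm >= s_prox & m$s_mm <= s_dist
  clean <- is.na(m$flags) | m$flags == ""
  used <- in_range & clean & !is.na(m$irregularity)
  if (!any(used)) {
    counts <- table(unlist(strsplit(m$flags[in_range & !clean], ";", fixed = TRUE)))
    stop(sprintf("no usable slices in [%.1f, %.1f] mm (%d in range; flags: %s)",
                 s_prox, s_dist, sum(in_range),
                 if (length(counts)) paste(names(counts), counts, sep = "=", collapse = ", ")
                 else "none"))
  }
  structure(list(score = mean(m$irregularity[used]),
                 n_slices_used = sum(used),
                 s_range = c(s_prox = s_prox, s_dist = s_dist),
                 slices = dplyr::mutate(m, used = used),
                 settings = settings),
            class = "shagginess_result")
}

#' @export
print.shagginess_result <- function(x, ...) {
  cat(sprintf("Shagginess score: %.3f\n", x$score))
  cat(sprintf("  slices used: %d of %d, arc length %.1f-%.1f mm\n",
              x$n_slices_used, nrow(x$slices), x$s_range[1L], x$s_range[2L]))
  flagged <- x$slices$flags[!is.na(x$slices$flags) & x$slices$flags != ""]
  if (length(flagged))
    cat(sprintf("  flagged slices: %d (%s)\n", length(flagged),
                paste(unique(flagged), collapse = ", ")))
  invisible(x)
}

#' Map landmark points to centerline arc lengths
#'
#' Each landmark (e.g. the level just distal to the left subclavian ostium,
#' and the level just above the celiac ostium, for thoracoabdominal scoring)
#' is snapped to the nearest centerline point; its arc length delimits the
#' scored segment. The pair is returned ordered, so proximal/distal may be
#' supplied in either order.
#'
#' @param cl a [centerline()].
#' @param proximal_pt,distal_pt world coordinates (mm).
#' @param max_dist_mm maximum allowed landmark-to-centerline distance
#'   (default 20 mm); beyond it the landmark is considered misplaced.
#' @return named numeric vector `c(s_prox, s_dist)` with `s_prox < s_dist`.
#' @export
landmarks_to_arclength <- function(cl, proximal_pt, distal_pt, max_dist_mm = 20) {
  stopifnot(inherits(cl, "centerline"))
  snap <- function(pt, label) {
    d2 <- rowSums(sweep(cl$points, 2L, as.numeric(pt))^2)
    i <- which.min(d2)
    d <- sqrt(d2[i])
    if (d > max_dist_mm)
      stop(sprintf("%s landmark is %.1f mm from the centerline (limit %.1f mm)",
                   label, d, max_dist_mm))
    cl$arclength[i]
  }
  s <- sort(c(snap(proximal_pt, "proximal"), snap(distal_pt, "distal")))
  if (s[1L] == s[2L]) stop("landmarks map to the same centerline point")
  c(s_prox = s[1L], s_dist = s[2L])
}
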