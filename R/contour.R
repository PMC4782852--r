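#' Construct a luminal cross-section contour
#'
#' A contour is a closed, simple, counter-clockwise planar polyline in mm,
#' representing the traced boundary of the lumen on one cross-sectional
#' (multiplanar reconstruction) image. The closing edge from the last vertex
#' back to the first is implicit: do not repeat the first vertex.
#'
#' @param points numeric matrix with two columns (x, y in mm) and at least
#'   three rows. A duplicated closing vertex is dropped. If the vertices are
#'   ordered clockwise they are reversed so that the stored orientation is
#'   always counter-clockwise (positive signed area).
#' @return an object of class `lumen_contour`: the vertex matrix with the
#'   orientation invariant enforced.
#' @examples
#' sq <- contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' perimeter(sq) # 4
#' @export
contour <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L)
    stop("contour points must be a numeric matrix with 2 columns (x, y in mm)")
  if (anyNA(points) || any(!is.finite(points)))
    stop("contour points must be finite")
  n <- nrow(points)
  if (n >= 2L && all(abs(points[n, ] - points[1L, ]) < 1e-12)) {
    points <- points[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 3L) stop("a contour needs at least 3 distinct vertices")
  a <- signed_area(points)
  if (abs(a) < 1e-12)
    stop("degenerate contour: signed area is zero")
  if (a < 0) points <- points[rev(seq_len(n)), , drop = FALSE]
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(points, class = c("lumen_contour", "matrix", "array"))
}

#' @export
print.lumen_contour <- function(x, ...) {
  cat(sprintf("<lumen_contour> %d vertices, perimeter %.3f mm, area %.3f mm^2\n",
              nrow(x), perimeter(x), signed_area(x)))
  invisible(x)
}

# shoelace signed area; > 0 for CCW
signed_area <- function(points) {
  x <- points[, 1L]; y <- points[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Contour perimeter
#'
#' The contour length `A`: the sum of Euclidean edge lengths including the
#' closing edge. This is the numerator of the circularity ratio.
#'
#' @param contour a [contour()] object (or a plain 2-column vertex matrix).
#' @return perimeter in mm.
#' @export
perimeter <- function(contour) {
  p <- as.matrix(contour)
  d <- p[c(seq_len(nrow(p))[-1L], 1L), , drop = FALSE] - p
  sum(sqrt(rowSums(d^2)))
}

edge_lengths <- function(points) {
  d <- points[c(seq_len(nrow(points))[-1L], 1L), , drop = FALSE] - points
  sqrt(rowSums(d^2))
}

#' Resample a contour to equally spaced vertices
#'
#' Redistributes vertices uniformly in arc length along the closed polyline.
#' All contours are resampled to a fixed vertex count before metrology so that
#' the polygonal perimeter is comparable across inputs of different native
#' resolution (the perimeter of a polygonal trace otherwise depends on how
#' densely it was digitized).
#'
#' @param contour a [contour()] object.
#' @param n_points number of output vertices (>= 16; default 720).
#' @return a [contour()] with exactly `n_points` vertices, orientation
#'   preserved and the first output vertex at the first input vertex.
#' @export
resample_contour <- function(contour, n_points = 720L) {
  p <- as.matrix(contour)
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 16L)
    stop("n_points must be an integer >= 16")
  len <- edge_lengths(p)
  total <- sum(len)
  if (total <= 0) stop("degenerate contour: zero perimeter")
  s <- c(0, cumsum(len))                      # arc length at each vertex, closed
  target <- total * (seq_len(n_points) - 1L) / n_points
  seg <- findInterval(target, s, rightmost.closed = TRUE)
  seg[seg > nrow(p)] <- nrow(p)
  frac <- (target - s[seg]) / pmax(len[seg], .Machine$double.eps)
  nxt <- c(seq_len(nrow(p))[-1L], 1L)
  out <- p[seg, , drop = FALSE] + frac * (p[nxt[seg], , drop = FALSE] - p[seg, , drop = FALSE])
  contour(out)
}

#' Measure through-center diameters over a fan of angles
#'
#' Casts paired rays from `center` at `n_angles` evenly spaced angles covering
#' a half turn (the default 180 angles step by 1 degree); the ray pair at angle
#' theta and theta + 180 degrees yields one diameter. Each half-diameter is the
#' distance to the crossing of the ray with the contour; for non-convex
#' contours with several crossings the `crossing` policy selects which one.
#' The mean of the fan is the effective diameter `B` used by the circularity
#' ratio.
#'
#' @param contour a [contour()] object.
#' @param center 2D point (mm) strictly inside the polygon. If it is not
#'   inside, an error of class `shag_center_outside` is signalled; callers may
#'   catch it and fall back to the contour centroid (the scoring pipeline does,
#'   and flags the slice).
#' @param n_angles number of diameters to measure (default 180).
#' @param crossing `"first"` (default) takes the nearest ray-boundary crossing
#'   on each side, so protrusions into the lumen narrow the measured diameter;
#'   `"farthest"` takes the outermost crossing.
#' @return an object of class `diameter_fan`: list with `center`, `n_angles`,
#'   `angles` (radians), `diameters` (mm) and `mean_diameter` (mm).
#' @export
diameter_fan <- function(contour, center, n_angles = 180L,
                         crossing = c("first", "farthest")) {
  crossing <- match.arg(crossing)
  p <- as.matrix(contour)
  center <- as.numeric(center)
  n_angles <- as.integer(n_angles)
  if (n_angles < 1L) stop("n_angles must be a positive integer")
  if (!point_in_polygon(center, p))
    stop(errorCondition(
      sprintf("diameter fan center (%.2f, %.2f) is not inside the contour",
              center[1L], center[2L]),
      class = c("shag_center_outside", "shag_error")))

  theta <- (seq_len(n_angles) - 1L) * pi / n_angles
  phi <- c(theta, theta + pi)                 # 2 * n_angles ray directions
  r <- ray_crossing_distances(p, center, phi, crossing)
  if (anyNA(r))
    stop(errorCondition("ray with no contour crossing: contour is not a valid simple polygon around the center",
                        class = "shag_error"))
  d <- r[seq_len(n_angles)] + r[n_angles + seq_len(n_angles)]
  structure(list(center = center, n_angles = n_angles, angles = theta,
                 diameters = d, mean_diameter = mean(d)),
            class = "diameter_fan")
}

#' @export
print.diameter_fan <- function(x, ...) {
  cat(sprintf("<diameter_fan> %d angles, mean diameter %.3f mm (range %.3f-%.3f)\n",
              x$n_angles, x$mean_diameter, min(x$diameters), max(x$diameters)))
  invisible(x)
}

# Distance from `center` to the selected crossing of each ray with the polygon
# boundary. `phi` is a vector of ray angles; fully vectorized over rays x edges.
ray_crossing_distances <- function(points, center, phi, crossing = "first") {
  a <- sweep(points, 2L, center)              # edge starts, relative to center
  nxt <- c(seq_len(nrow(points))[-1L], 1L)
  e <- points[nxt, , drop = FALSE] - points   # edge vectors
  dx <- cos(phi); dy <- sin(phi)
  # solve a + s*e = t*d  =>  t = cross(a, e)/cross(d, e), s = cross(a, d)/cross(d, e)
  den <- outer(dx, e[, 2L]) - outer(dy, e[, 1L])          # cross(d, e): rays x edges
  num_t <- a[, 1L] * e[, 2L] - a[, 2L] * e[, 1L]          # cross(a, e): per edge
  num_s <- outer(dy, a[, 1L]) - outer(dx, a[, 2L])        # cross(a, d): rays x edges
  ok <- abs(den) > 1e-14
  tt <- sweep(1 / ifelse(ok, den, NA_real_), 2L, num_t, `*`)
  ss <- num_s / ifelse(ok, den, NA_real_)
  # small tolerance on the edge parameter so a ray passing exactly through a
  # vertex cannot fall between the two adjacent edges' half-open ranges
  hit <- ok & !is.na(tt) & tt > 1e-12 & ss >= -1e-9 & ss < 1 + 1e-9
  tt[!hit] <- NA_real_
  if (crossing == "first") {
    suppressWarnings(res <- apply(tt, 1L, min, na.rm = TRUE))
  } else {
    suppressWarnings(res <- apply(tt, 1L, max, na.rm = TRUE))
  }
  res[!is.finite(res)] <- NA_real_
  res
}

# even-odd point-in-polygon test
point_in_polygon <- function(pt, points) {
  x <- points[, 1L]; y <- points[, 2L]
  nxt <- c(seq_len(nrow(points))[-1L], 1L)
  x2 <- x[nxt]; y2 <- y[nxt]
  cross <- ((y > pt[2L]) != (y2 > pt[2L]))
  if (!any(cross)) return(FALSE)
  xi <- x[cross] + (pt[2L] - y[cross]) / (y2[cross] - y[cross]) * (x2[cross] - x[cross])
  sum(xi > pt[1L]) %% 2L == 1L
}

# area centroid of a simple polygon
contour_centroid <- function(points) {
  points <- as.matrix(points)
  x <- points[, 1L]; y <- points[, 2L]
  nxt <- c(seq_len(nrow(points))[-1L], 1L)
  cr <- x * y[nxt] - x[nxt] * y
  a <- sum(cr) / 2
  c(sum((x + x[nxt]) * cr), sum((y + y[nxt]) * cr)) / (6 * a)
}

#' Circularity ratio C
#'
#' The ratio of the contour length `A` to the circumference of a perfect
#' circle whose diameter is the mean through-center diameter `B`:
#' `C = A / (pi * B)`. For any contour measured through an interior point,
#' `C >= 1` up to discretization error, with equality for a circle.
#'
#' @param perimeter_A contour length in mm (> 0).
#' @param mean_diameter_B mean diameter in mm (> 0).
#' @param pi_value value of pi to use. Defaults to full machine precision;
#'   set `pi_value = 3.14` to replicate workstation-style two-decimal
#'   arithmetic (the difference in C is about 0.05%).
#' @return the dimensionless ratio C.
#' @export
circularity_ratio <- function(perimeter_A, mean_diameter_B, pi_value = pi) {
  if (!is.numeric(perimeter_A) || !is.numeric(mean_diameter_B) ||
      any(perimeter_A <= 0) || any(mean_diameter_B <= 0))
    stop("perimeter A and mean diameter B must be positive")
  perimeter_A / (pi_value * mean_diameter_B)
}

#' Per-slice irregularity contribution
#'
#' Maps the circularity ratio to the per-slice score contribution
#' `(C - 1) * 100`; a perfect circle contributes 0, and the shagginess score
#' is the mean of this quantity over the scored slices.
#'
#' @param C circularity ratio (> 0).
#' @return `(C - 1) * 100`.
#' @export
slice_irregularity <- function(C) {
  if (!is.numeric(C) || any(C <= 0)) stop("C must be positive")
  (C - 1) * 100
}
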