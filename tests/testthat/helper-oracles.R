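# Independent brute-force oracles: deliberately scalar, loop-based
# re-derivations of the geometric quantities, sharing no code with the
# package's vectorized implementations.

# edge-summation perimeter
oracle_perimeter <- function(pts) {
  n <- nrow(pts)
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    total <- total + sqrt(sum((pts[j, ] - pts[i, ])^2))
  }
  total
}

# exhaustive ray-segment intersection: distance from center to the chosen
# crossing of the ray at angle phi with the closed polygon
oracle_ray_distance <- function(pts, center, phi, crossing = "first") {
  n <- nrow(pts)
  d <- c(cos(phi), sin(phi))
  best <- if (crossing == "first") Inf else -Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- pts[i, ] - center
    e <- pts[j, ] - pts[i, ]
    den <- d[1L] * e[2L] - d[2L] * e[1L]
    if (abs(den) < 1e-14) next
    # from a + s e = t d:  cross with e gives t, cross with d gives s
    t <- (a[1L] * e[2L] - a[2L] * e[1L]) / den
    s <- (a[1L] * d[2L] - a[2L] * d[1L]) / den
    if (t > 1e-12 && s >= -1e-9 && s < 1 + 1e-9) {
      if (crossing == "first") best <- min(best, t) else best <- max(best, t)
    }
  }
  if (is.infinite(best)) NA_real_ else best
}

oracle_fan_mean <- function(pts, center, n_angles = 180L, crossing = "first") {
  total <- 0
  for (i in seq_len(n_angles)) {
    th <- (i - 1L) * pi / n_angles
    total <- total + oracle_ray_distance(pts, center, th, crossing) +
      oracle_ray_distance(pts, center, th + pi, crossing)
  }
  total / n_angles
}

# random star-shaped polygon about the origin: smooth positive radius from a
# low-order random Fourier series
random_star_polygon <- function(n_vertices = 256L, R = 10, n_harm = 5L, amp = 0.12) {
  th <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  r <- rep(1, n_vertices)
  for (h in seq_len(n_harm))
    r <- r + stats::runif(1, 0, amp / h) * sin(h * th + stats::runif(1, 0, 2 * pi))
  cbind(R * r * cos(th), R * r * sin(th))
}

# ellipse boundary quadrature through stats::integrate (adaptive, a different
# method from the package's periodic trapezoid rule)
oracle_ellipse <- function(a, b) {
  A <- stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                        0, 2 * pi, rel.tol = 1e-10)$value
  B <- stats::integrate(function(t) a * b / sqrt((b * cos(t))^2 + (a * sin(t))^2),
                        0, 2 * pi, rel.tol = 1e-10)$value / pi
  list(A = A, B = B, C = A / (pi * B), irregularity = (A / (pi * B) - 1) * 100)
}

# arc-length + paired-chord quadrature for a polar curve r(theta), again via
# stats::integrate
oracle_polar_C <- function(rfun, drfun) {
  A <- stats::integrate(function(t) sqrt(rfun(t)^2 + drfun(t)^2),
                        0, 2 * pi, rel.tol = 1e-10)$value
  B <- stats::integrate(rfun, 0, 2 * pi, rel.tol = 1e-10)$value / pi
  A / (pi * B)
}
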