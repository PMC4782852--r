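test_that("contour construction enforces the closed-CCW invariants", {
  sq_cw <- contour(cbind(c(0, 0, 1, 1), c(0, 1, 1, 0)))   # clockwise input
  expect_gt(shagginess:::signed_area(sq_cw), 0)            # reversed to CCW
  # duplicated closing vertex dropped
  tri <- contour(cbind(c(0, 1, 0, 0), c(0, 0, 1, 0)))
  expect_equal(nrow(tri), 3L)
  expect_error(contour(cbind(c(0, 1), c(0, 0))), "at least 3")
  expect_error(contour(cbind(c(0, 1, 2), c(0, 0, 0))), "degenerate")
  expect_error(contour(cbind(c(0, 1, NA), c(0, 0, 1))), "finite")
})

test_that("resampling redistributes vertices without changing the polyline", {
  sq <- contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  rs <- resample_contour(sq, 16L)
  expect_equal(nrow(rs), 16L)
  expect_equal(perimeter(rs), 4.0, tolerance = 1e-12)
  gaps <- shagginess:::edge_lengths(as.matrix(rs))
  expect_lt(max(gaps) - min(gaps), 1e-12)

  # a 32-gon trace of a circle: resampled vertices stay on the polyline, so
  # the perimeter stays at the inscribed-32-gon closed form (up to corners
  # cut where 720 is not a multiple of 32), within 0.2% of the circle
  c32 <- ngon(32L, R = 10)
  c720 <- resample_contour(c32, 720L)
  expect_equal(perimeter(c720), 2 * 32 * 10 * sin(pi / 32), tolerance = 2e-4)
  expect_lt(abs(perimeter(c720) - 2 * pi * 10) / (2 * pi * 10), 0.002)
  # when the counts divide evenly every corner is kept and it is exact
  expect_equal(perimeter(resample_contour(c32, 96L)), 2 * 32 * 10 * sin(pi / 32),
               tolerance = 1e-12)

  expect_error(resample_contour(sq, 8L), ">= 16")
})

test_that("perimeter matches closed forms and quadrature", {
  expect_equal(perimeter(contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))), 4.0)
  expect_equal(perimeter(ngon(720L, R = 10)), 2 * 720 * 10 * sin(pi / 720),
               tolerance = 1e-12)
  # plain-loop oracle agreement on an irregular polygon
  set.seed(7)
  poly <- random_star_polygon(101L)
  expect_equal(perimeter(contour(poly)), oracle_perimeter(poly), tolerance = 1e-12)
  # dense polygonal ellipse against adaptive quadrature of the arc length
  ell <- polar_contour(function(t) 15 * 10 / sqrt((10 * cos(t))^2 + (15 * sin(t))^2),
                       n = 4096L)
  expect_equal(perimeter(ell), oracle_ellipse(15, 10)$A, tolerance = 1e-3)
})

test_that("diameter fan matches closed forms for circle and ellipse", {
  circ <- ngon(2880L, R = 10)
  fan <- diameter_fan(circ, c(0, 0))
  expect_equal(fan$n_angles, 180L)
  expect_equal(length(fan$diameters), 180L)
  expect_true(all(abs(fan$diameters - 20) < 1e-4))
  expect_equal(fan$mean_diameter, mean(fan$diameters))

  # offset center in a circle: d(phi) = 2 sqrt(R^2 - delta^2 sin^2 phi)
  fan_off <- diameter_fan(circ, c(2, 0))
  expect_equal(fan_off$diameters, 2 * sqrt(100 - 4 * sin(fan_off$angles)^2),
               tolerance = 1e-5)

  ell <- polar_contour(function(t) 15 * 10 / sqrt((10 * cos(t))^2 + (15 * sin(t))^2),
                       n = 4096L)
  fan_e <- diameter_fan(ell, c(0, 0))
  expect_equal(fan_e$mean_diameter, oracle_ellipse(15, 10)$B, tolerance = 5e-3)

  expect_error(diameter_fan(circ, c(50, 0)), class = "shag_center_outside")
})

test_that("diameter fan and perimeter agree with the brute-force oracle on random star polygons", {
  set.seed(42)
  for (rep in 1:50) {
    poly <- random_star_polygon(round(stats::runif(1, 64, 256)))
    ct <- contour(poly)
    p <- as.matrix(ct)
    expect_equal(perimeter(ct), oracle_perimeter(p), tolerance = 1e-12)
    fan <- diameter_fan(ct, c(0, 0), n_angles = 45L)
    expect_equal(fan$mean_diameter, oracle_fan_mean(p, c(0, 0), 45L),
                 tolerance = 1e-6)
  }
})

test_that("first vs farthest crossing policies differ only for non-convex contours", {
  # crescent-like: deep inward bump makes some rays cross the wall thrice
  rfun <- function(t) 10 - 6 * exp(-((t - pi) / 0.25)^2 / 2)
  ct <- polar_contour(rfun, 1440L)
  f1 <- diameter_fan(ct, c(0, 0), crossing = "first")
  f2 <- diameter_fan(ct, c(0, 0), crossing = "farthest")
  expect_true(all(f2$diameters >= f1$diameters - 1e-9))
  # star-shaped about the center, so first crossing equals r(theta)
  expect_equal(f1$diameters,
               rfun(f1$angles) + rfun(f1$angles + pi), tolerance = 1e-3)
  conv <- ngon(720L)
  fc1 <- diameter_fan(conv, c(1, 2), crossing = "first")
  fc2 <- diameter_fan(conv, c(1, 2), crossing = "farthest")
  expect_equal(fc1$diameters, fc2$diameters, tolerance = 1e-9)
})

test_that("circularity ratio and irregularity follow their definitions", {
  expect_equal(circularity_ratio(62.8319, 20.0), 62.8319 / (pi * 20), tolerance = 1e-12)
  expect_equal(circularity_ratio(pi * 20, 20.0), 1.0, tolerance = 1e-12)
  # workstation-style two-decimal pi on request
  expect_equal(circularity_ratio(62.8, 20, pi_value = 3.14), 62.8 / (3.14 * 20))
  expect_error(circularity_ratio(-1, 20), "positive")
  expect_error(circularity_ratio(60, 0), "positive")

  expect_equal(slice_irregularity(1.0), 0.0)
  expect_equal(slice_irregularity(1.0825), 8.25, tolerance = 1e-12)
  expect_equal(slice_irregularity(1.12441), 12.441, tolerance = 1e-12)
  expect_error(slice_irregularity(-0.5), "positive")
})

test_that("perimeter is rigid-motion invariant and C is scale invariant", {
  set.seed(11)
  poly <- random_star_polygon(180L)
  ct <- contour(poly)
  ang <- 0.7
  Rm <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2L)
  moved <- contour(sweep(poly %*% Rm, 2L, c(13, -4), `+`))
  expect_equal(perimeter(moved), perimeter(ct), tolerance = 1e-9)

  C1 <- circularity_ratio(perimeter(ct), diameter_fan(ct, c(0, 0))$mean_diameter)
  sc <- contour(poly * 3.7)
  C2 <- circularity_ratio(perimeter(sc), diameter_fan(sc, c(0, 0))$mean_diameter)
  expect_equal(C2, C1, tolerance = 1e-9)
})

test_that("C >= 1 for convex contours measured through an interior point", {
  # the circle stand-in is a 2880-gon so that polygonal chord shortening
  # stays well below the 1e-6 band even if rays align with vertices
  shapes <- list(ngon(2880L, R = 10),
                 polar_contour(function(t) 15 * 10 / sqrt((10 * cos(t))^2 + (15 * sin(t))^2), 1440L),
                 ngon(5L, R = 8), ngon(7L, R = 8), ngon(64L, R = 3))
  for (ct in shapes) {
    for (cen in list(c(0, 0), c(0.5, -0.8))) {
      C <- circularity_ratio(perimeter(ct), diameter_fan(ct, cen)$mean_diameter)
      expect_gte(C, 1 - 1e-6)
    }
  }
})

test_that("C increases strictly with lobe amplitude", {
  Cs <- vapply(c(0, 0.02, 0.05, 0.10), function(eps) {
    ct <- polar_contour(function(t) 10 * (1 + eps * sin(8 * t)), 1440L)
    circularity_ratio(perimeter(ct), diameter_fan(ct, c(0, 0))$mean_diameter)
  }, numeric(1))
  expect_true(all(diff(Cs) > 0))
  # exact quadrature value at the largest amplitude, and the small-amplitude
  # expansion C ~ 1 + k^2 eps^2 / 4 where it is valid
  expect_equal(Cs[4L],
               oracle_polar_C(function(t) 10 * (1 + 0.10 * sin(8 * t)),
                              function(t) 10 * 0.10 * 8 * cos(8 * t)),
               tolerance = 1e-4)
  expect_equal(Cs[2L], 1 + 64 * 0.02^2 / 4, tolerance = 1e-3)
})
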