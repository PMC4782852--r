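test_that("frames along a straight line are constant with normals on the tangent", {
  cl <- centerline(cbind(0, 0, seq(0, 30, by = 1.5)))
  fr <- plane_frames(cl)
  expect_true(all(abs(fr$normal - matrix(c(0, 0, 1), nrow(fr$normal), 3, byrow = TRUE)) < 1e-9))
  expect_true(all(abs(sweep(fr$u, 2L, fr$u[1L, ])) < 1e-9))
  expect_true(all(abs(sweep(fr$v, 2L, fr$v[1L, ])) < 1e-9))
  # right-handed orthonormal triads
  for (i in c(1L, nrow(fr$u))) {
    f <- frame_at(fr, i)
    expect_lt(abs(sum(f$u * f$v)), 1e-9)
    expect_lt(abs(sum(f$u * f$normal)), 1e-9)
    expect_equal(sum(shagginess:::cross3(f$u, f$v) * f$normal), 1, tolerance = 1e-9)
  }
})

test_that("parallel-transport frames do not flip around a 90-degree arc", {
  th <- seq(0, pi / 2, length.out = 61L)
  cl <- centerline(cbind(60 * cos(th), 0, 60 * sin(th)))
  fr <- plane_frames(cl)
  dots <- rowSums(fr$u[-1L, ] * fr$u[-nrow(fr$u), ])
  expect_true(all(dots > 0))
  ang <- acos(pmin(1, dots)) * 180 / pi
  expect_true(all(ang < 30))
  # on a planar arc the out-of-plane axis is parallel-transported unchanged:
  # whichever in-plane axis starts off-plane keeps its off-plane component
  expect_true(all(abs(fr$u %*% c(0, 1, 0) - fr$u[1L, 2L]) < 1e-6 |
                  abs(fr$v %*% c(0, 1, 0) - fr$v[1L, 2L]) < 1e-6))
})

test_that("single-point centerlines are rejected", {
  expect_error(centerline(cbind(0, 0, 0)), "n >= 2")
  expect_error(centerline(rbind(c(0, 0, 0), c(0, 0, 0))), "repeated")
})

test_that("plane sampling is exact on constant volumes and outside the grid", {
  vol <- volume_grid(array(1, c(10, 10, 10)))
  f <- list(origin = c(4.5, 4.5, 4.5), normal = c(0, 0, 1),
            u = c(1, 0, 0), v = c(0, 1, 0), s = 0)
  img <- sample_plane(vol, f, half_extent_mm = 3, grid_spacing_mm = 0.5)
  expect_true(all(img$values == 1))
  expect_equal(dim(img$values), c(13L, 13L))
  f_out <- f; f_out$origin <- c(500, 500, 500)
  img_out <- sample_plane(vol, f_out, 3, 0.5)
  expect_true(all(img_out$values == 0))
})

test_that("a perpendicular cut through a tube recovers the disk area", {
  ph <- rasterize_phantom(phantom_spec("straight", 40, cross_section("circle", R = 10)))
  mid <- ph$truth$centerline[which.min(abs(ph$truth$centerline_s - 20)), ]
  f <- list(origin = mid, normal = c(0, 0, 1), u = c(1, 0, 0), v = c(0, 1, 0), s = 20)
  img <- sample_plane(ph$volume, f, 16, 0.25)
  area <- sum(img$values >= 0.5) * 0.25^2
  expect_lt(abs(area - pi * 100) / (pi * 100), 0.02)
})

test_that("contour extraction is sub-pixel accurate and selects the enclosing component", {
  g <- seq(-16, 16, by = 0.25)
  ramp <- function(m) matrix(pmin(1, pmax(0, m)), length(g), length(g))
  dist1 <- sqrt(outer(g, rep(1, length(g)))^2 + outer(rep(1, length(g)), g)^2)
  disk <- structure(list(x = g, y = g, values = ramp(0.5 + (10 - dist1) / 0.5)),
                    class = "mpr_image")
  ct <- extract_lumen_contour(disk)
  expect_equal(nrow(ct), 720L)
  expect_lt(abs(perimeter(ct) - 2 * pi * 10) / (2 * pi * 10), 0.005)

  # two disjoint disks: the one enclosing the requested center is returned
  d_a <- sqrt(outer(g + 8, rep(1, length(g)))^2 + outer(rep(1, length(g)), g)^2)
  d_b <- sqrt(outer(g - 8, rep(1, length(g)))^2 + outer(rep(1, length(g)), g)^2)
  two <- structure(list(x = g, y = g,
                        values = pmax(ramp(0.5 + (5 - d_a) / 0.5),
                                      ramp(0.5 + (5 - d_b) / 0.5))),
                   class = "mpr_image")
  ct_b <- extract_lumen_contour(two, center_mm = c(8, 0))
  cen <- shagginess:::contour_centroid(ct_b)
  expect_equal(cen[1L], 8, tolerance = 0.05)
  expect_equal(cen[2L], 0, tolerance = 0.05)

  blank <- structure(list(x = g, y = g,
                          values = matrix(0, length(g), length(g))),
                     class = "mpr_image")
  expect_error(extract_lumen_contour(blank), class = "shag_no_contour")
})

test_that("halving the in-plane grid changes a smooth perimeter by under 0.3%", {
  ph <- rasterize_phantom(phantom_spec("straight", 40,
                                       cross_section("lobed", R = 10, epsilon = 0.05, k = 6L)))
  mid <- ph$truth$centerline[which.min(abs(ph$truth$centerline_s - 20)), ]
  f <- list(origin = mid, normal = c(0, 0, 1), u = c(1, 0, 0), v = c(0, 1, 0), s = 20)
  p <- vapply(c(0.5, 0.25), function(gs)
    perimeter(extract_lumen_contour(sample_plane(ph$volume, f, 16, gs))), numeric(1))
  expect_lt(abs(p[2L] - p[1L]) / p[1L], 0.003)
})
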