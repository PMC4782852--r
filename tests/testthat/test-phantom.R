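test_that("analytic circularity oracle reproduces closed forms", {
  expect_equal(analytic_C(cross_section("circle", R = 7)), 1, tolerance = 1e-10)
  expect_equal(analytic_C(cross_section("ellipse", a = 12, b = 12)), 1, tolerance = 1e-10)
  # against an independent adaptive-quadrature oracle
  an <- analytic_section(cross_section("ellipse", a = 15, b = 10))
  orc <- oracle_ellipse(15, 10)
  expect_equal(an$A, orc$A, tolerance = 1e-7)
  expect_equal(an$B, orc$B, tolerance = 1e-7)
  expect_equal(an$C, orc$C, tolerance = 1e-8)
  # lobed small-amplitude expansion: C ~ 1 + k^2 eps^2 / 4
  Cl <- analytic_C(cross_section("lobed", R = 10, epsilon = 0.05, k = 8L))
  expect_equal(Cl, 1.04, tolerance = 0.01)
  expect_equal(Cl, oracle_polar_C(function(t) 10 * (1 + 0.05 * sin(8 * t)),
                                  function(t) 10 * 0.05 * 8 * cos(8 * t)),
               tolerance = 1e-8)
})

test_that("one inward bump strictly raises circularity", {
  base <- cross_section("circle", R = 12.5)
  bumped <- cross_section("bumped", R = 12.5,
                          bumps = list(list(angle = 1.0, width = 0.25, height = 2)))
  expect_gt(analytic_C(bumped), analytic_C(base))
})

test_that("invalid sections are rejected", {
  expect_error(cross_section("lobed", R = 10, epsilon = 0.6, k = 6L), "star-shaped")
  expect_error(cross_section("lobed", R = 10, epsilon = 0.1, k = 1L), "k must be")
  expect_error(cross_section("bumped", R = 5,
                             bumps = list(list(angle = 0, width = 0.5, height = 6))),
               "positive")
  expect_error(cross_section("ellipse", a = -1, b = 10), "positive")
})

test_that("rasterization matches the analytic tube volume and is deterministic", {
  true_vol <- pi * 100 * 60
  # strict binary rasterization: foreground count vs the analytic tube volume
  bin <- rasterize_phantom(phantom_spec("straight", 60, cross_section("circle", R = 10),
                                        antialias = FALSE))
  expect_lt(abs(sum(bin$volume$voxels) - true_vol) / true_vol, 0.02)
  # anti-aliased rasterization: fractional occupancy integrates to the volume
  spec <- phantom_spec("straight", 60, cross_section("circle", R = 10))
  ph <- rasterize_phantom(spec)
  expect_lt(abs(sum(ph$volume$voxels) - true_vol) / true_vol, 0.02)
  ph2 <- rasterize_phantom(spec)
  expect_identical(ph$volume$voxels, ph2$volume$voxels)
  expect_identical(ph$volume$affine, ph2$volume$affine)

  expect_error(phantom_spec("straight", 10, cross_section("circle", R = 5),
                            voxel_mm = 1), "too short")
})

test_that("phantom ground-truth table carries the analytic per-slice circularity", {
  spec <- phantom_spec("straight", 60, cross_section("lobed", R = 10, epsilon = 0.1, k = 6L))
  ph <- rasterize_phantom(spec)
  expect_equal(unique(ph$truth$table$C), ph$truth$C)
  expect_equal(ph$truth$irregularity, (ph$truth$C - 1) * 100, tolerance = 1e-12)
  expect_equal(ph$truth$C,
               oracle_polar_C(function(t) 10 * (1 + 0.1 * sin(6 * t)),
                              function(t) 10 * 0.1 * 6 * cos(6 * t)),
               tolerance = 1e-8)
})

test_that("full pipeline reproduces the lobed-tube oracle within 2%", {
  out <- run_phantom_pipeline(
    phantom_spec("straight", 60, cross_section("lobed", R = 10, epsilon = 0.1, k = 6L)))
  expect_lt(abs(out$result$score - out$truth$irregularity) / out$truth$irregularity, 0.02)
})

test_that("a blurred phantom still scores close to its oracle", {
  out <- run_phantom_pipeline(
    phantom_spec("straight", 60, cross_section("lobed", R = 10, epsilon = 0.1, k = 6L),
                 blur_sigma_mm = 0.6))
  # partial-volume blur rounds the lobes slightly; the score must stay in the
  # right neighbourhood rather than collapse
  expect_gt(out$result$score, 0.8 * out$truth$irregularity)
  expect_lt(out$result$score, 1.1 * out$truth$irregularity)
})

test_that("helix-path phantoms rasterize and score like their section", {
  spec <- phantom_spec("helix", length = 70, section = cross_section("circle", R = 6),
                       helix_radius_mm = 30, helix_pitch_mm = 40, margin_mm = 4)
  out <- run_phantom_pipeline(spec, half_extent_mm = 12)
  expect_lt(abs(out$result$score), 0.5)
})

test_that("random bumps are reproducible from their seed", {
  b1 <- random_bumps(3, seed = 99)
  b2 <- random_bumps(3, seed = 99)
  expect_identical(b1, b2)
  expect_length(b1, 3L)
  sec <- cross_section("bumped", R = 12, bumps = b1)
  expect_gt(analytic_C(sec), 1)
})
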