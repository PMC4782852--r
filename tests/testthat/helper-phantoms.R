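# shared phantom-pipeline runner for tests: compact volumes, fine in-plane
# grid, landmarks from the phantom's own inset suggestions
run_phantom_pipeline <- function(spec, grid_spacing_mm = 0.25,
                                 half_extent_mm = 16, ...) {
  ph <- rasterize_phantom(spec)
  cfg <- run_config(ph$volume, "mask",
                    seed_proximal = ph$truth$seeds$proximal,
                    seed_distal = ph$truth$seeds$distal,
                    landmark_proximal = ph$truth$landmarks$proximal,
                    landmark_distal = ph$truth$landmarks$distal,
                    half_extent_mm = half_extent_mm,
                    grid_spacing_mm = grid_spacing_mm, ...)
  res <- run_pipeline(cfg)
  list(result = res, truth = ph$truth, volume = ph$volume)
}

rotation_about <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3L], -a[2L], -a[3L], 0, a[1L], a[2L], -a[1L], 0), 3L, 3L)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# regular n-gon contour inscribed in a circle
ngon <- function(n, R = 10, center = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  contour(cbind(center[1L] + R * cos(th), center[2L] + R * sin(th)))
}

polar_contour <- function(rfun, n = 720L) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  r <- rfun(th)
  contour(cbind(r * cos(th), r * sin(th)))
}
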