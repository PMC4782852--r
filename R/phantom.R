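#' Parametric cross-section of a synthetic vessel
#'
#' Cross-sections are star-shaped polar curves `r(theta)` about the
#' centerline, which keeps the through-center chord well-posed and makes the
#' analytic circularity oracle a one-dimensional quadrature. Families:
#'
#' * `circle`: `r = R`.
#' * `ellipse`: semi-axes `a`, `b`.
#' * `lobed`: `r = R (1 + epsilon sin(k theta))` — a smooth multi-lobed wall,
#'   the canonical irregularity model (small-amplitude expansion
#'   `C ~ 1 + k^2 epsilon^2 / 4`).
#' * `bumped`: a circle with Gaussian protrusions into the lumen, emulating
#'   discrete mural plaque.
#'
#' @param family one of `"circle"`, `"ellipse"`, `"lobed"`, `"bumped"`.
#' @param R base radius in mm (circle, lobed, bumped).
#' @param a,b ellipse semi-axes in mm.
#' @param epsilon lobe amplitude as a fraction of `R` (`0 <= epsilon < 0.5`
#'   keeps the curve star-shaped).
#' @param k integer lobe count (>= 2).
#' @param bumps list of `list(angle, width, height)` protrusions: center
#'   angle (radians), angular standard deviation (radians), inward height (mm).
#' @return an object of class `cross_section`.
#' @export
cross_section <- function(family = c("circle", "ellipse", "lobed", "bumped"),
                          R = 10, a = 15, b = 10, epsilon = 0.05, k = 8L,
                          bumps = list()) {
  family <- match.arg(family)
  if (family == "lobed") {
    if (epsilon < 0 || epsilon >= 0.5)
      stop("lobed sections need 0 <= epsilon < 0.5 to stay star-shaped")
    if (k < 2L || k != round(k)) stop("lobe count k must be an integer >= 2")
  }
  if (family == "ellipse" && (a <= 0 || b <= 0)) stop("ellipse semi-axes must be positive")
  if (family %in% c("circle", "lobed", "bumped") && R <= 0) stop("R must be positive")
  sec <- structure(list(family = family, R = R, a = a, b = b,
                        epsilon = epsilon, k = as.integer(k), bumps = bumps),
                   class = "cross_section")
  th <- seq(0, 2 * pi, length.out = 4096L)
  if (any(section_radius(sec, th) <= 0))
    stop("radius function r(theta) must be strictly positive everywhere")
  sec
}

#' @rdname cross_section
#' @param section a `cross_section`.
#' @param theta angles in radians (vectorized).
#' @return `section_radius()` returns `r(theta)` in mm.
#' @export
section_radius <- function(section, theta) {
  r <- switch(section$family,
    circle = rep(section$R, length(theta)),
    ellipse = {
      a <- section$a; b <- section$b
      a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
    },
    lobed = section$R * (1 + section$epsilon * sin(section$k * theta)),
    bumped = {
      r0 <- rep(section$R, length(theta))
      for (bp in section$bumps) {
        # wrapped angular distance to the bump center
        d <- atan2(sin(theta - bp$angle), cos(theta - bp$angle))
        r0 <- r0 - bp$height * exp(-d^2 / (2 * bp$width^2))
      }
      r0
    })
  r
}

# dr/dtheta by central differences (used only to normalize the signed
# distance when rasterizing; quadrature accuracy is set by the grid density)
section_radius_deriv <- function(section, theta, h = 1e-5) {
  (section_radius(section, theta + h) - section_radius(section, theta - h)) / (2 * h)
}

#' Analytic circularity of a parametric cross-section
#'
#' The oracle the whole pipeline is validated against: `A` by arc-length
#' quadrature of the parametric boundary, `B` by quadrature of paired
#' through-center chords (`d(theta) = r(theta) + r(theta + pi)`, the
#' first-crossing policy, exact for star-shaped curves), and `C = A / (pi B)`.
#' Quadrature uses the periodic trapezoid rule on a dense uniform grid, which
#' converges spectrally for these smooth periodic integrands (well below the
#' 1e-8 tolerance at the default grid).
#'
#' @param section a [cross_section()].
#' @param n_quad quadrature nodes (default 16384).
#' @return `analytic_section()` returns a list with `A`, `B`, `C` and
#'   `irregularity`; `analytic_C()` returns just `C`.
#' @export
analytic_section <- function(section, n_quad = 16384L) {
  th <- 2 * pi * (seq_len(n_quad) - 1L) / n_quad
  r <- section_radius(section, th)
  if (any(r <= 0)) stop("section is not star-shaped: r(theta) <= 0")
  dr <- section_radius_deriv(section, th)
  A <- mean(sqrt(r^2 + dr^2)) * 2 * pi
  B <- 2 * mean(r)            # mean over theta of r(theta) + r(theta + pi)
  C <- A / (pi * B)
  list(A = A, B = B, C = C, irregularity = (C - 1) * 100)
}

#' @rdname analytic_section
#' @export
analytic_C <- function(section, n_quad = 16384L) analytic_section(section, n_quad)$C

#' Specify a synthetic vessel phantom
#'
#' A phantom is a tube swept along a parametric path with a fixed
#' [cross_section()], rasterized onto a voxel grid with analytically known
#' per-slice circularity. Paths: `straight` (along +z), `arc` (planar
#' circular bend), `helix`. An optional rigid pose (rotation + translation)
#' re-orients the whole phantom in the scanner frame, which is how the
#' pipeline's rotation invariance is exercised.
#'
#' @param path `"straight"`, `"arc"` or `"helix"`.
#' @param length tube length along the path in mm.
#' @param section a [cross_section()].
#' @param voxel_mm isotropic voxel size in mm (default 1, typical CT slice
#'   thickness).
#' @param bend_radius_mm arc path: bend radius in mm (default 60).
#' @param helix_radius_mm,helix_pitch_mm helix path parameters.
#' @param rotation 3x3 rotation matrix posing the phantom in world space.
#' @param translation length-3 world offset in mm.
#' @param antialias if `TRUE` (default) voxels near the wall get fractional
#'   occupancy from a clamped signed-distance ramp one voxel wide, emulating
#'   partial-volume averaging and keeping the 0.5 iso-surface on the true
#'   boundary; if `FALSE` the volume is strictly binary.
#' @param blur_sigma_mm optional additional Gaussian blur (mm) of the
#'   occupancy field, a rough stand-in for the scanner point-spread function.
#' @param margin_mm empty border around the tube (default 6).
#' @param seed integer recorded with the phantom for provenance
#'   (rasterization itself is deterministic).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(path = c("straight", "arc", "helix"), length = 150,
                         section = cross_section("circle", R = 10),
                         voxel_mm = 1, bend_radius_mm = 60,
                         helix_radius_mm = 30, helix_pitch_mm = 40,
                         rotation = NULL, translation = c(0, 0, 0),
                         antialias = TRUE, blur_sigma_mm = 0,
                         margin_mm = 6, seed = NULL) {
  path <- match.arg(path)
  stopifnot(inherits(section, "cross_section"))
  if (length <= 0 || voxel_mm <= 0) stop("length and voxel_mm must be positive")
  if (length / voxel_mm < 20)
    stop("phantom too short: need length / voxel_mm >= 20 slices' worth of tube")
  if (path == "arc" && length > bend_radius_mm * 2 * pi)
    stop("arc length exceeds a full turn of the bend circle")
  if (!is.null(rotation)) {
    rotation <- as.matrix(rotation)
    if (!all(dim(rotation) == c(3L, 3L)) ||
        max(abs(crossprod(rotation) - diag(3))) > 1e-8)
      stop("rotation must be a 3x3 orthonormal matrix")
  }
  structure(list(path = path, length = length, section = section,
                 voxel_mm = voxel_mm, bend_radius_mm = bend_radius_mm,
                 helix_radius_mm = helix_radius_mm, helix_pitch_mm = helix_pitch_mm,
                 rotation = rotation, translation = as.numeric(translation),
                 antialias = isTRUE(antialias), blur_sigma_mm = blur_sigma_mm,
                 margin_mm = margin_mm, seed = seed),
            class = "phantom_spec")
}

# canonical-frame path sample at arc lengths s: point, tangent, in-plane axes
phantom_path <- function(spec, s) {
  switch(spec$path,
    straight = list(p = cbind(0, 0, s),
                    t = cbind(0, 0, rep(1, length(s))),
                    u = cbind(1, 0, rep(0, length(s))),
                    v = cbind(0, 1, rep(0, length(s)))),
    arc = {
      Rb <- spec$bend_radius_mm
      ph <- s / Rb
      list(p = cbind(Rb * cos(ph), 0, Rb * sin(ph)),
           t = cbind(-sin(ph), 0, cos(ph)),
           u = cbind(cos(ph), 0, sin(ph)),     # radial, points away from bend center
           v = cbind(0, rep(1, length(s)), 0))
    },
    helix = {
      Rh <- spec$helix_radius_mm
      c0 <- spec$helix_pitch_mm / (2 * pi)
      sp <- sqrt(Rh^2 + c0^2)
      tt <- s / sp
      tg <- cbind(-Rh * sin(tt), Rh * cos(tt), c0) / sp
      u <- cbind(cos(tt), sin(tt), 0 * tt)
      v <- cbind(tg[, 2L] * u[, 3L] - tg[, 3L] * u[, 2L],
                 tg[, 3L] * u[, 1L] - tg[, 1L] * u[, 3L],
                 tg[, 1L] * u[, 2L] - tg[, 2L] * u[, 1L])
      list(p = cbind(Rh * cos(tt), Rh * sin(tt), c0 * tt), t = tg, u = u, v = v)
    })
}

phantom_max_radius <- function(section) {
  th <- seq(0, 2 * pi, length.out = 4096L)
  max(section_radius(section, th))
}

#' Rasterize a phantom into a volume with ground truth
#'
#' Produces the voxel volume and, alongside it, everything the phantom knows
#' analytically: the true centerline, seed points for centerline extraction,
#' the exact per-slice circularity from [analytic_section()], and suggested
#' scoring landmarks inset from the tube ends (slices within roughly a lumen
#' diameter of the open ends see the end caps and are not representative).
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` (a [volume_grid()]) and `truth`: list
#'   with `centerline` (dense true axis, world mm), `seeds` (proximal/distal
#'   world points just inside the tube), `landmarks` (inset scoring range
#'   endpoints on the axis), `C`, `irregularity`, `A`, `B`, and `table`
#'   (tibble of per-slice `s_mm`, `C`, `irregularity` at 1 mm steps).
#' @export
rasterize_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sec <- spec$section
  rmax <- phantom_max_radius(sec)
  ramp <- spec$voxel_mm                        # signed-distance ramp half-width
  pad <- rmax + spec$margin_mm

  # pose
  rot <- if (is.null(spec$rotation)) diag(3) else spec$rotation
  trn <- spec$translation
  to_world <- function(p) sweep(p %*% t(rot), 2L, trn, `+`)

  # bounding box from a dense path sampling
  sd <- seq(0, spec$length, by = spec$voxel_mm / 4)
  pw <- to_world(phantom_path(spec, sd)$p)
  lo <- apply(pw, 2L, min) - pad
  hi <- apply(pw, 2L, max) + pad
  dims <- pmax(ceiling((hi - lo) / spec$voxel_mm) + 1L, 2L)
  affine <- diag(c(rep(spec$voxel_mm, 3), 1))
  # half-voxel origin offset: voxel centers sit at generic (half-integer)
  # positions relative to the phantom axis, as in real scans, instead of
  # exactly on the axis/boundary lattice
  affine[1:3, 4L] <- lo + spec$voxel_mm / 2
  lo <- lo + spec$voxel_mm / 2

  # voxel centers in the canonical phantom frame
  idx <- as.matrix(expand.grid(i = seq_len(dims[1L]) - 1L,
                               j = seq_len(dims[2L]) - 1L,
                               k = seq_len(dims[3L]) - 1L))
  wpts <- sweep(idx * spec$voxel_mm, 2L, lo, `+`)
  cpts <- sweep(wpts, 2L, trn) %*% rot         # inverse pose: R^T (p - t)

  d <- phantom_signed_distance(spec, cpts)
  vox <- if (spec$antialias) pmin(1, pmax(0, 0.5 + d / (2 * ramp))) else as.numeric(d > 0)
  vol <- volume_grid(array(vox, dim = dims), affine = affine)
  if (spec$blur_sigma_mm > 0)
    vol$voxels <- gauss_blur_3d(vol$voxels, spec$blur_sigma_mm / spec$voxel_mm)

  an <- analytic_section(sec)
  inset <- max(10, 2 * rmax * 0.8)
  s_marks <- c(inset, spec$length - inset)
  pp <- phantom_path(spec, c(2 * spec$voxel_mm, spec$length - 2 * spec$voxel_mm, s_marks))
  pw2 <- to_world(pp$p)
  s_tab <- seq(0, spec$length, by = 1)
  list(volume = vol,
       truth = list(
         centerline = to_world(phantom_path(spec, sd)$p),
         centerline_s = sd,
         seeds = list(proximal = pw2[1L, ], distal = pw2[2L, ]),
         landmarks = list(proximal = pw2[3L, ], distal = pw2[4L, ],
                          s = s_marks),
         A = an$A, B = an$B, C = an$C, irregularity = an$irregularity,
         table = tibble::tibble(s_mm = s_tab, C = an$C,
                                irregularity = an$irregularity)))
}

# signed distance (mm, positive inside) from canonical-frame points to the
# tube surface; exact for the lateral wall of straight tubes with circular
# sections, first-order accurate (gradient-normalized) otherwise — ample for
# a one-voxel anti-aliasing ramp.
phantom_signed_distance <- function(spec, cpts) {
  x <- cpts[, 1L]; y <- cpts[, 2L]; z <- cpts[, 3L]
  L <- spec$length
  if (spec$path == "straight") {
    s <- z
    uu <- x; vv <- y
  } else if (spec$path == "arc") {
    Rb <- spec$bend_radius_mm
    ph <- atan2(z, x)
    s <- Rb * ph
    phc <- pmin(pmax(ph, 0), L / Rb)
    uu <- cos(phc) * x + sin(phc) * z - Rb     # radial offset from the axis
    vv <- y
  } else {
    Rh <- spec$helix_radius_mm
    c0 <- spec$helix_pitch_mm / (2 * pi)
    sp <- sqrt(Rh^2 + c0^2)
    tt <- z / c0                               # initial guess from height
    for (it in 1:8) {                          # Newton on d/dt |p - q(t)|^2 = 0
      ct <- cos(tt); st <- sin(tt)
      f  <- Rh * (x * st - y * ct) + c0 * (c0 * tt - z)
      fp <- Rh * (x * ct + y * st) + c0^2
      tt <- tt - f / pmax(fp, 1e-6)
    }
    s <- tt * sp
    ttc <- pmin(pmax(tt, 0), L / sp)
    qu <- cbind(cos(ttc), sin(ttc))
    uu <- x * qu[, 1L] + y * qu[, 2L] - Rh
    tg <- cbind(-Rh * sin(ttc), Rh * cos(ttc), rep(c0, length(ttc))) / sp
    u3 <- cbind(qu, 0)
    v3 <- cbind(tg[, 2L] * u3[, 3L] - tg[, 3L] * u3[, 2L],
                tg[, 3L] * u3[, 1L] - tg[, 1L] * u3[, 3L],
                tg[, 1L] * u3[, 2L] - tg[, 2L] * u3[, 1L])
    qp <- cbind(Rh * cos(ttc), Rh * sin(ttc), c0 * ttc)
    rel <- cbind(x, y, z) - qp
    vv <- rowSums(rel * v3)
    uu <- rowSums(rel * u3) # recompute cleanly against the clamped point
  }
  th <- atan2(vv, uu)
  rho <- sqrt(uu^2 + vv^2)
  rb <- section_radius(spec$section, th)
  drb <- section_radius_deriv(spec$section, th)
  d_lat <- (rb - rho) / sqrt(1 + (drb / rb)^2)
  d_cap <- pmin(s, L - s)
  pmin(d_lat, d_cap)
}

# separable Gaussian blur of a 3D array; sigma in voxels
gauss_blur_3d <- function(arr, sigma_vox) {
  half <- max(1L, ceiling(3 * sigma_vox))
  off <- -half:half
  w <- exp(-off^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  dm <- dim(arr)
  for (axis in 1:3) {
    out <- array(0, dm)
    for (m in seq_along(off)) {
      o <- off[m]
      src <- pmin(pmax(seq_len(dm[axis]) + o, 1L), dm[axis])  # replicate edges
      out <- out + w[m] * switch(axis,
        arr[src, , , drop = FALSE],
        arr[, src, , drop = FALSE],
        arr[, , src, drop = FALSE])
    }
    arr <- out
  }
  arr
}

#' Read a phantom specification from JSON
#'
#' The JSON mirrors the [phantom_spec()] / [cross_section()] arguments, e.g.
#' `{"path": "straight", "length": 150, "voxel_mm": 1,
#'   "section": {"family": "lobed", "R": 10, "epsilon": 0.05, "k": 6}}`.
#'
#' @param path JSON file path.
#' @return a [phantom_spec()].
#' @export
phantom_spec_from_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$section)) stop("phantom JSON needs a 'section' object")
  sec_args <- j$section
  if (!is.null(sec_args$bumps) && is.data.frame(sec_args$bumps))
    sec_args$bumps <- lapply(seq_len(nrow(sec_args$bumps)),
                             function(i) as.list(sec_args$bumps[i, ]))
  section <- do.call(cross_section, sec_args)
  args <- j[setdiff(names(j), "section")]
  args$section <- section
  if (!is.null(args$rotation)) args$rotation <- matrix(unlist(args$rotation), 3L, 3L, byrow = TRUE)
  do.call(phantom_spec, args)
}

#' Random inward plaque bumps for a bumped cross-section
#'
#' @param n_bumps number of protrusions.
#' @param seed RNG seed (required, for reproducible phantoms).
#' @param height_range inward height range in mm.
#' @param width_range angular standard deviation range in radians.
#' @return a `bumps` list for [cross_section()].
#' @export
random_bumps <- function(n_bumps, seed, height_range = c(1, 3),
                         width_range = c(0.1, 0.3)) {
  stopifnot(n_bumps >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  lapply(seq_len(n_bumps), function(i)
    list(angle = stats::runif(1, 0, 2 * pi),
         width = stats::runif(1, width_range[1L], width_range[2L]),
         height = stats::runif(1, height_range[1L], height_range[2L])))
}
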