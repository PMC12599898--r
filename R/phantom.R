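#' Analytic digital phantom scene
#'
#' A piecewise-analytic 3D Hounsfield-unit field: a background value, an
#' optional affine-in-z ramp, and a list of primitives (ellipsoids and
#' axis-aligned z-slabs) that either replace or add to the value underneath.
#' The scene is evaluable at any continuous (x, y, z) in mm, deterministically,
#' which is what makes dense-quadrature ground truth possible: the phantom
#' stands in for a real paired thin/thick acquisition with the continuous
#' object known exactly.
#'
#' @param background Background HU value.
#' @param primitives List of primitives from [ellipsoid()] / [z_slab()].
#' @param extent 2 x 3 matrix: rows (min, max), columns (x, y, z) bounding
#'   box in mm.
#' @param z_ramp HU per mm added as `z_ramp * z` to the background.
#' @return An object of class `phantom_scene`.
#' @export
phantom_scene <- function(background = 0, primitives = list(),
                          extent = rbind(c(-100, -100, -50), c(100, 100, 50)),
                          z_ramp = 0) {
  extent <- matrix(as.numeric(extent), nrow = 2L)
  if (any(extent[2L, ] <= extent[1L, ])) {
    stop("extent max must exceed min on every axis", call. = FALSE)
  }
  structure(list(background = background, primitives = primitives,
                 extent = extent, z_ramp = z_ramp),
            class = "phantom_scene")
}

#' Ellipsoid primitive for a phantom scene
#'
#' @param center Length-3 (x, y, z) center in mm.
#' @param semiaxes Length-3 positive semi-axes in mm.
#' @param value HU value of the primitive.
#' @param mode `"replace"` (value overrides what is underneath) or `"add"`.
#' @return A primitive list for [phantom_scene()].
#' @export
ellipsoid <- function(center, semiaxes, value, mode = c("replace", "add")) {
  stopifnot(length(center) == 3L, length(semiaxes) == 3L, all(semiaxes > 0))
  list(type = "ellipsoid", center = as.numeric(center),
       semiaxes = as.numeric(semiaxes), value = value,
       mode = match.arg(mode))
}

#' Axis-aligned z-slab primitive for a phantom scene
#'
#' Covers all (x, y) for `z_lo <= z < z_hi`; used for piecewise-constant-in-z
#' content such as the step wedge.
#'
#' @param z_lo,z_hi Slab bounds in mm (`z_hi > z_lo`).
#' @inheritParams ellipsoid
#' @return A primitive list for [phantom_scene()].
#' @export
z_slab <- function(z_lo, z_hi, value, mode = c("replace", "add")) {
  stopifnot(z_hi > z_lo)
  list(type = "z_slab", z_lo = z_lo, z_hi = z_hi, value = value,
       mode = match.arg(mode))
}

#' Evaluate a phantom scene at continuous points
#'
#' @param scene A [phantom_scene()].
#' @param x,y,z Equal-length numeric vectors of coordinates in mm.
#' @return Numeric vector of HU values.
#' @export
scene_eval <- function(scene, x, y, z) {
  stopifnot(inherits(scene, "phantom_scene"))
  n <- max(length(x), length(y), length(z))
  x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
  v <- rep(scene$background, n) + scene$z_ramp * z
  for (p in scene$primitives) {
    inside <- switch(p$type,
      ellipsoid = ((x - p$center[1L]) / p$semiaxes[1L])^2 +
                  ((y - p$center[2L]) / p$semiaxes[2L])^2 +
                  ((z - p$center[3L]) / p$semiaxes[3L])^2 <= 1,
      z_slab = z >= p$z_lo & z < p$z_hi,
      stop("unknown primitive type: ", p$type, call. = FALSE)
    )
    if (p$mode == "replace") v[inside] <- p$value else v[inside] <- v[inside] + p$value
  }
  v
}

.grid_xy <- function(rows, cols, spacing) {
  # pixel centers, grid centered on the origin
  xr <- (seq_len(rows) - (rows + 1) / 2) * spacing[1L]
  xc <- (seq_len(cols) - (cols + 1) / 2) * spacing[2L]
  list(x = matrix(rep(xc, each = rows), nrow = rows),   # col coordinate -> x
       y = matrix(rep(xr, times = cols), nrow = rows))  # row coordinate -> y
}

.check_geom_in_extent <- function(scene, zmin, zmax) {
  ez <- scene$extent[, 3L]
  if (zmin < ez[1L] - 1e-9 || zmax > ez[2L] + 1e-9) {
    stop(sprintf("requested z range [%g, %g] mm falls outside the scene extent [%g, %g] mm",
                 zmin, zmax, ez[1L], ez[2L]), call. = FALSE)
  }
}

#' Render a thin-slice acquisition of a phantom scene
#'
#' Forward model for the thin acquisition: each slice at center `l` is the
#' boxcar (uniform) average of the scene over the slab
#' `[l - t/2, l + t/2]`, approximated by `subsamples` uniformly spaced
#' z-evaluations; each pixel is evaluated at its center. The boxcar slab is
#' deliberately a different axial profile from the triangular one used for
#' thick-slice ground truth, so the simulator is tested on approximating a
#' profile it does not trivially share with its input.
#'
#' @param scene A [phantom_scene()].
#' @param geom A [slice_geometry()] for the thin series (thickness = slab
#'   width).
#' @param rows,cols In-plane grid size.
#' @param spacing Length-2 (row, col) pixel spacing in mm.
#' @param subsamples Odd integer >= 1; quadrature points across the slab.
#' @return An [axial_volume()].
#' @export
render_thin <- function(scene, geom, rows = 64L, cols = 64L,
                        spacing = c(1, 1), subsamples = 11L) {
  stopifnot(inherits(scene, "phantom_scene"), inherits(geom, "slice_geometry"))
  if (subsamples < 1L || subsamples %% 2L == 0L) {
    stop("`subsamples` must be an odd integer >= 1", call. = FALSE)
  }
  locs <- slice_locations(geom)
  t <- geom$thickness
  .check_geom_in_extent(scene, min(locs) - t / 2, max(locs) + t / 2)
  offs <- if (subsamples == 1L) 0 else seq(-t / 2, t / 2, length.out = subsamples)
  .render(scene, locs, offs, rep(1 / subsamples, subsamples),
          rows, cols, spacing, t)
}

#' Render ground-truth thick slices of a phantom scene
#'
#' The oracle the weighted-sum simulator approximates from discrete thin
#' slices: each slice at center `p` is the triangularly weighted average of
#' the continuous scene over `[p - t, p + t]`, with weight
#' `max(0, 1 - |z - p| / t)`, computed by dense quadrature and normalised by
#' the integrated weight.
#'
#' @inheritParams render_thin
#' @param subsamples Odd integer >= 3; quadrature points across `[p-t, p+t]`
#'   (use >= 101 for oracle-grade accuracy — an order of magnitude denser
#'   than the thin rendering it judges).
#' @return An [axial_volume()].
#' @export
render_truth_thick <- function(scene, geom, rows = 64L, cols = 64L,
                               spacing = c(1, 1), subsamples = 101L) {
  stopifnot(inherits(scene, "phantom_scene"), inherits(geom, "slice_geometry"))
  if (subsamples < 3L || subsamples %% 2L == 0L) {
    stop("`subsamples` must be an odd integer >= 3", call. = FALSE)
  }
  locs <- slice_locations(geom)
  t <- geom$thickness
  .check_geom_in_extent(scene, min(locs) - t, max(locs) + t)
  offs <- seq(-t, t, length.out = subsamples)
  w <- pmax(0, 1 - abs(offs) / t)
  .render(scene, locs, offs, w / sum(w), rows, cols, spacing, t)
}

.render <- function(scene, locs, offs, weights, rows, cols, spacing, thickness) {
  g <- .grid_xy(rows, cols, spacing)
  vox <- array(0, dim = c(rows, cols, length(locs)))
  for (k in seq_along(locs)) {
    acc <- matrix(0, rows, cols)
    for (j in seq_along(offs)) {
      z <- locs[k] + offs[j]
      acc <- acc + weights[j] *
        matrix(scene_eval(scene, as.vector(g$x), as.vector(g$y),
                          rep(z, rows * cols)), nrow = rows)
    }
    vox[, , k] <- acc
  }
  axial_volume(vox, positions = locs, thickness = thickness, spacing = spacing)
}

#' Add seeded Gaussian acquisition noise to a volume
#'
#' Models the thickness dependence of CT noise: with `thickness_scaling`,
#' the effective sigma is `sigma_hu * sqrt(t_ref / t)` with `t_ref = 1` mm —
#' thinner slices integrate fewer photons and are noisier.
#'
#' @param vol An [axial_volume()].
#' @param sigma_hu Noise standard deviation in HU at the 1 mm reference
#'   thickness (`>= 0`).
#' @param seed Integer seed; the same seed reproduces the same noise field.
#' @param thickness_scaling Scale sigma by `sqrt(t_ref / t)`?
#' @return An [axial_volume()] with noise added; attribute `"noise_seed"`
#'   records the seed used.
#' @export
add_noise <- function(vol, sigma_hu, seed, thickness_scaling = TRUE) {
  stopifnot(inherits(vol, "axial_volume"), sigma_hu >= 0)
  if (sigma_hu == 0) return(vol)
  sigma_eff <- if (thickness_scaling) sigma_hu * sqrt(1 / vol$thickness) else sigma_hu
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  noisy <- vol$voxels + array(rnorm(length(vol$voxels), sd = sigma_eff),
                              dim = dim(vol$voxels))
  out <- axial_volume(noisy, positions = vol$positions,
                      thickness = vol$thickness, spacing = vol$spacing)
  attr(out, "noise_seed") <- as.integer(seed)
  out
}

#' Named phantom presets
#'
#' Deterministic scenes spanning the content regimes that matter for slice
#' simulation: `"blobs"` (smooth soft-tissue-like ellipsoids in a water
#' background), `"step_wedge"` (piecewise constant in z — edge-dominated),
#' `"ramp"` (HU affine in z at 10 HU/mm — gradient content) and
#' `"shepp_like"` (a skull-like shell with interior structures).
#'
#' @param name Preset name.
#' @return A [phantom_scene()].
#' @export
preset_scene <- function(name = c("blobs", "step_wedge", "ramp", "shepp_like")) {
  name <- match.arg(name)
  ext <- rbind(c(-100, -100, -60), c(100, 100, 110))
  switch(name,
    blobs = phantom_scene(
      background = 0, extent = ext,
      primitives = list(
        ellipsoid(c(0, 0, 20), c(45, 40, 35), 60),
        ellipsoid(c(-12, 8, 12), c(14, 12, 16), 35, mode = "add"),
        ellipsoid(c(15, -10, 26), c(10, 16, 12), -45, mode = "add"),
        ellipsoid(c(5, 14, 30), c(6, 6, 8), 90, mode = "add")
      )),
    step_wedge = phantom_scene(
      background = -1000, extent = ext,
      primitives = list(
        z_slab(0, 10, 0), z_slab(10, 20, 100),
        z_slab(20, 30, 300), z_slab(30, 40, 700)
      )),
    ramp = phantom_scene(background = 0, z_ramp = 10, extent = ext),
    shepp_like = phantom_scene(
      background = -1000, extent = ext,
      primitives = list(
        ellipsoid(c(0, 0, 20), c(70, 55, 45), 900),           # skull shell
        ellipsoid(c(0, 0, 20), c(64, 49, 40), 40),            # brain
        ellipsoid(c(-18, 5, 20), c(12, 20, 15), 20),          # ventricle-ish
        ellipsoid(c(18, 5, 20), c(12, 20, 15), 20),
        ellipsoid(c(0, -20, 25), c(5, 5, 5), 120, mode = "add")
      ))
  )
}
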