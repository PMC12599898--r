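#' Triangular slice-sensitivity weight
#'
#' Weight of a thin slice at position `l` contributing to a thick slice
#' centered at `p`, for slice thickness `t`:
#' `g(p, l, t) = max(0, 1 - |p - l| / t)`.
#'
#' The triangular profile models the slice sensitivity of weighted filtered
#' back projection: contribution is maximal for the coincident slice and
#' falls off linearly to zero at axial distance `t`. The weight is symmetric
#' in `p` and `l`.
#'
#' @param p Thick-slice center z (mm); vectorised.
#' @param l Thin-slice center z (mm); vectorised.
#' @param t Slice thickness (mm, `> 0`).
#' @return Weights in `[0, 1]`, recycled to the common length of `p` and `l`.
#' @examples
#' triangular_weight(1.5, 1.0, 2.0)  # 0.75
#' @export
triangular_weight <- function(p, l, t) {
  if (length(t) != 1L || !is.finite(t) || t <= 0) {
    stop("slice thickness `t` must be a single positive number", call. = FALSE)
  }
  pmax(0, 1 - abs(p - l) / t)
}

#' Simulate thick slices by triangular-weighted summation
#'
#' The physically grounded thick-slice simulator. Target slice centers are
#' placed in patient coordinates by [slice_locations()]; each thick slice is
#' the weighted sum of all thin slices, with weights from
#' [triangular_weight()] at the target thickness, normalised by the total
#' weight. Weights are computed and accumulated in double precision and
#' normalisation happens once per output slice, after accumulation.
#'
#' A target location where no thin slice carries positive weight (a gap in
#' the thin series wider than the thickness) is a hard error — silently
#' skipping it would corrupt the output grid.
#'
#' @param thin An [axial_volume()] of thin slices.
#' @param geom A [slice_geometry()] for the target thick series.
#' @return An [axial_volume()] with positions `slice_locations(geom)` and
#'   thickness `geom$thickness`. Every output voxel lies within the
#'   \[min, max\] envelope of the contributing thin voxels at that pixel.
#' @export
simulate_proposed <- function(thin, geom) {
  stopifnot(inherits(thin, "axial_volume"), inherits(geom, "slice_geometry"))
  targets <- slice_locations(geom)
  d <- dim(thin$voxels)
  # weight matrix: thin slices x target locations
  w <- outer(thin$positions, targets,
             function(l, p) triangular_weight(p, l, geom$thickness))
  w_total <- colSums(w)
  if (any(w_total == 0)) {
    bad <- targets[w_total == 0]
    stop(sprintf(
      "no thin slice within thickness %g mm of target location(s) %s mm: gap in thin coverage",
      geom$thickness, paste(format(bad), collapse = ", ")), call. = FALSE)
  }
  flat <- matrix(thin$voxels, nrow = d[1L] * d[2L], ncol = d[3L])
  out <- flat %*% w
  out <- sweep(out, 2L, w_total, "/")
  axial_volume(array(out, dim = c(d[1L], d[2L], length(targets))),
               positions = targets, thickness = geom$thickness,
               spacing = thin$spacing)
}

#' Simulate thick slices by direct downsampling
#'
#' The nearest-neighbour baseline: keeps every `factor`-th thin slice
#' (indices 0, factor, 2*factor, ... in 0-based terms) and relabels the
#' result with `factor` times the thin thickness. Deliberately index-based:
#' kept positions are whatever the kept thin slices had, reproducing the
#' center-slice misplacement of the prior work it stands in for.
#'
#' @param thin An [axial_volume()].
#' @param factor Positive integer decimation factor.
#' @return An [axial_volume()] with the kept slices.
#' @export
simulate_direct_downsample <- function(thin, factor) {
  stopifnot(inherits(thin, "axial_volume"))
  factor <- .check_factor(factor)
  keep <- seq.int(1L, n_slices(thin), by = factor)
  axial_volume(thin$voxels[, , keep, drop = FALSE],
               positions = thin$positions[keep],
               thickness = factor * thin$thickness,
               spacing = thin$spacing)
}

#' Simulate thick slices by simple averaging
#'
#' The linear-interpolation baseline: non-overlapping groups of `factor`
#' consecutive thin slices are averaged with equal weights. The output
#' position is the mean of the group positions (for even `factor` there is
#' no middle slice). A trailing remainder group smaller than `factor` is
#' dropped.
#'
#' @inheritParams simulate_direct_downsample
#' @return An [axial_volume()] with `floor(n / factor)` slices.
#' @export
simulate_simple_average <- function(thin, factor) {
  stopifnot(inherits(thin, "axial_volume"))
  factor <- .check_factor(factor)
  n <- n_slices(thin)
  n_groups <- n %/% factor
  if (n_groups < 1L) {
    stop(sprintf("slice count (%d) is smaller than the averaging factor (%d)",
                 n, factor), call. = FALSE)
  }
  d <- dim(thin$voxels)
  flat <- matrix(thin$voxels, nrow = d[1L] * d[2L], ncol = n)
  grp <- rep(seq_len(n_groups), each = factor)
  idx <- seq_len(n_groups * factor)
  # group-mean via matrix product with the averaging indicator
  A <- matrix(0, nrow = n, ncol = n_groups)
  A[cbind(idx, grp)] <- 1 / factor
  out <- flat %*% A
  pos <- as.vector(tapply(thin$positions[idx], grp, mean))
  axial_volume(array(out, dim = c(d[1L], d[2L], n_groups)),
               positions = pos, thickness = factor * thin$thickness,
               spacing = thin$spacing)
}

#' Simulate thick slices by Gaussian filtering and decimation
#'
#' The Gaussian-interpolation baseline: a 1-D discrete Gaussian (sigma in
#' slice units, truncated at 4 sigma and renormalised to sum 1) is run along
#' the slice axis, then the result is decimated exactly as
#' [simulate_direct_downsample()]. Near the volume ends the kernel is
#' renormalised over its in-bounds support, so constants are preserved
#' everywhere.
#'
#' @inheritParams simulate_direct_downsample
#' @param sigma Gaussian standard deviation in slice units (`> 0`). Defaults
#'   to `factor / 2`.
#' @return An [axial_volume()] with the kept slices.
#' @export
simulate_gaussian_average <- function(thin, sigma = factor / 2, factor = 1L) {
  stopifnot(inherits(thin, "axial_volume"))
  factor <- .check_factor(factor)
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("`sigma` must be a single positive number (slice units)", call. = FALSE)
  }
  n <- n_slices(thin)
  r <- max(1L, ceiling(4 * sigma))
  kern <- dnorm(seq.int(-r, r), sd = sigma)
  kern <- kern / sum(kern)
  d <- dim(thin$voxels)
  flat <- matrix(thin$voxels, nrow = d[1L] * d[2L], ncol = n)
  # banded convolution matrix, renormalised at the edges
  C <- matrix(0, nrow = n, ncol = n)
  for (off in seq.int(-r, r)) {
    j <- seq_len(n) + off
    ok <- j >= 1L & j <= n
    C[cbind(j[ok], seq_len(n)[ok])] <- kern[off + r + 1L]
  }
  C <- sweep(C, 2L, colSums(C), "/")
  smoothed <- flat %*% C
  keep <- seq.int(1L, n, by = factor)
  axial_volume(array(smoothed[, keep], dim = c(d[1L], d[2L], length(keep))),
               positions = thin$positions[keep],
               thickness = factor * thin$thickness,
               spacing = thin$spacing)
}

#' Voxelwise difference map between two matched volumes
#'
#' Computes `a - b` voxel by voxel, preserving geometry, for exporting the
#' error patterns that distinguish simulation methods visually (index-based
#' baselines leave smooth edge-following errors; the weighted-sum method
#' leaves mostly noise).
#'
#' @param a,b [axial_volume()]s with identical shape and positions
#'   (within 1e-6 mm).
#' @return An [axial_volume()] holding `a$voxels - b$voxels`.
#' @export
difference_map <- function(a, b) {
  stopifnot(inherits(a, "axial_volume"), inherits(b, "axial_volume"))
  if (!identical(dim(a$voxels), dim(b$voxels))) {
    stop("volumes differ in shape: ",
         paste(dim(a$voxels), collapse = "x"), " vs ",
         paste(dim(b$voxels), collapse = "x"), call. = FALSE)
  }
  if (max(abs(a$positions - b$positions)) > 1e-6) {
    stop("volumes differ in slice positions; match them first (see match_positions)",
         call. = FALSE)
  }
  axial_volume(a$voxels - b$voxels, positions = a$positions,
               thickness = a$thickness, spacing = a$spacing)
}

#' Run any of the four simulation methods from one config
#'
#' Convenience dispatcher over the proposed weighted-sum simulator and the
#' three baselines, so pipelines and the command-line tool can switch method
#' by name.
#'
#' @param thin An [axial_volume()].
#' @param method One of `"proposed"`, `"direct_downsample"`,
#'   `"simple_average"`, `"gaussian_average"`.
#' @param geom A [slice_geometry()] (required for `"proposed"`).
#' @param factor Integer decimation/averaging factor (baselines).
#' @param sigma Gaussian sigma in slice units (`"gaussian_average"` only).
#' @return An [axial_volume()].
#' @export
simulate_thick <- function(thin, method = c("proposed", "direct_downsample",
                                            "simple_average", "gaussian_average"),
                           geom = NULL, factor = 1L, sigma = factor / 2) {
  method <- match.arg(method)
  switch(method,
    proposed = {
      if (is.null(geom)) stop("`geom` is required for the proposed method", call. = FALSE)
      simulate_proposed(thin, geom)
    },
    direct_downsample = simulate_direct_downsample(thin, factor),
    simple_average = simulate_simple_average(thin, factor),
    gaussian_average = simulate_gaussian_average(thin, sigma = sigma, factor = factor)
  )
}

.check_factor <- function(factor) {
  if (length(factor) != 1L || !is.finite(factor) || factor < 1 ||
      factor != round(factor)) {
    stop("`factor` must be a single integer >= 1", call. = FALSE)
  }
  as.integer(factor)
}
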