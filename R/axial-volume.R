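#' Axial CT volume with physical slice positions
#'
#' The common currency of all simulation stages: a 3D intensity grid in
#' Hounsfield units together with the physical z-coordinate of every slice
#' center, in mm, in the DICOM patient-based coordinate system. All axial
#' arithmetic downstream (slice placement, weighting, matching) is done on
#' these positions, never on slice indices.
#'
#' @param voxels 3D numeric array indexed `[row, col, slice]`, values in HU.
#' @param positions Numeric vector of per-slice z-coordinates (mm), strictly
#'   increasing, one per slice.
#' @param thickness Nominal slice thickness in mm (`> 0`). Distinct from the
#'   slice interval: consecutive positions may be closer than `thickness`
#'   (overlapping slices) or farther apart (gapped slices).
#' @param spacing Length-2 numeric, in-plane (row, col) pixel spacing in mm.
#'
#' @return An object of class `axial_volume`.
#' @export
axial_volume <- function(voxels, positions, thickness, spacing = c(1, 1)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3D array indexed [row, col, slice]", call. = FALSE)
  }
  n_slices <- dim(voxels)[3L]
  if (n_slices < 1L) stop("volume must contain at least one slice", call. = FALSE)
  positions <- as.numeric(positions)
  if (length(positions) != n_slices) {
    stop(sprintf("length(positions) [%d] != number of slices [%d]",
                 length(positions), n_slices), call. = FALSE)
  }
  if (anyNA(positions)) stop("positions must not contain NA", call. = FALSE)
  if (n_slices > 1L && any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  thickness <- as.numeric(thickness)
  if (length(thickness) != 1L || !is.finite(thickness) || thickness <= 0) {
    stop("`thickness` must be a single positive number (mm)", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be two positive numbers (row, col) in mm", call. = FALSE)
  }
  structure(
    list(voxels = voxels, positions = positions, thickness = thickness,
         spacing = spacing),
    class = "axial_volume"
  )
}

#' @export
print.axial_volume <- function(x, ...) {
  d <- dim(x$voxels)
  n <- d[3L]
  iv <- if (n > 1L) format(round(mean(diff(x$positions)), 4)) else "NA"
  cat(sprintf("<axial_volume> %d x %d pixels, %d slice%s\n",
              d[1L], d[2L], n, if (n == 1L) "" else "s"))
  cat(sprintf("  z: %s .. %s mm (mean interval %s mm)\n",
              format(round(x$positions[1L], 4)),
              format(round(x$positions[n], 4)), iv))
  cat(sprintf("  thickness: %s mm, in-plane spacing: %s x %s mm\n",
              format(x$thickness), format(x$spacing[1L]), format(x$spacing[2L])))
  cat(sprintf("  HU range: [%s, %s]\n",
              format(round(min(x$voxels), 2)), format(round(max(x$voxels), 2))))
  invisible(x)
}

#' @export
dim.axial_volume <- function(x) dim(x$voxels)

n_slices <- function(vol) dim(vol$voxels)[3L]

#' Extract one axial slice as a matrix
#'
#' @param vol An [axial_volume()].
#' @param i Slice index (1-based).
#' @return Numeric matrix `[row, col]`.
#' @export
get_slice <- function(vol, i) {
  stopifnot(inherits(vol, "axial_volume"))
  i <- as.integer(i)
  if (i < 1L || i > n_slices(vol)) stop("slice index out of range", call. = FALSE)
  vol$voxels[, , i]
}

#' Summarise an axial volume as a one-row tibble
#'
#' @param x An [axial_volume()].
#' @param ... Unused.
#' @return A one-row tibble with dimensions, z-range, interval and thickness.
#' @method glance axial_volume
#' @export
glance.axial_volume <- function(x, ...) {
  d <- dim(x$voxels)
  tibble::tibble(
    rows = d[1L], cols = d[2L], slices = d[3L],
    z_start = x$positions[1L], z_end = x$positions[d[3L]],
    interval = if (d[3L] > 1L) mean(diff(x$positions)) else NA_real_,
    thickness = x$thickness,
    hu_min = min(x$voxels), hu_max = max(x$voxels)
  )
}
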