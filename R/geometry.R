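#' Acquisition geometry of a target slice series
#'
#' Bundles the four parameters that define where simulated thick slices live
#' in the patient coordinate system: start position `s`, end position `e`,
#' slice interval `d` and slice thickness `t`, all in mm. Interval and
#' thickness are independent: `t > d` gives overlapping slices (common in
#' clinical thick-slice reconstructions), `t < d` gives gaps.
#'
#' @param start,end First and last candidate slice-center z (mm), `end >= start`.
#' @param interval Distance between consecutive slice centers (mm, `> 0`).
#' @param thickness Slice thickness (mm, `> 0`).
#' @return An object of class `slice_geometry`.
#' @export
slice_geometry <- function(start, end, interval, thickness) {
  vals <- c(start = start, end = end, interval = interval, thickness = thickness)
  if (any(!is.finite(vals))) stop("all geometry parameters must be finite", call. = FALSE)
  if (interval <= 0) stop("slice interval must be > 0 (got ", interval, ")", call. = FALSE)
  if (thickness <= 0) stop("slice thickness must be > 0 (got ", thickness, ")", call. = FALSE)
  if (end < start) {
    stop(sprintf("end position (%g) must be >= start position (%g)", end, start),
         call. = FALSE)
  }
  structure(
    list(start = as.numeric(start), end = as.numeric(end),
         interval = as.numeric(interval), thickness = as.numeric(thickness)),
    class = "slice_geometry"
  )
}

#' @export
print.slice_geometry <- function(x, ...) {
  cat(sprintf("<slice_geometry> z %g .. %g mm, interval %g mm, thickness %g mm (%d slices)\n",
              x$start, x$end, x$interval, x$thickness,
              length(slice_locations(x))))
  invisible(x)
}

# Inclusive-endpoint tolerance: guarantees `end` is kept when (end-start)/interval
# is integral despite floating-point representation of the bound.
.loc_eps <- 1e-6

#' Determine simulated thick-slice locations
#'
#' Walks from the start position in steps of the slice interval and keeps every
#' point up to and including the end position. Locations are physical
#' z-coordinates in mm, never slice indices: this is the position correction
#' that distinguishes the physically grounded simulation from index-based
#' downsampling, which misplaces slice centers whenever the thick-series grid
#' does not land on thin-slice indices.
#'
#' Locations are generated in closed form (`start + k * interval`) rather than
#' by repeated addition, so no floating-point drift accumulates over long
#' series; the inclusive endpoint is honoured to a 1e-6 mm tolerance.
#'
#' @param geom A [slice_geometry()].
#' @return Numeric vector of slice-center z (mm), first element exactly
#'   `geom$start`, consecutive differences exactly `geom$interval`.
#' @examples
#' slice_locations(slice_geometry(0, 10, 2, 3))  # 0 2 4 6 8 10
#' @export
slice_locations <- function(geom) {
  stopifnot(inherits(geom, "slice_geometry"))
  k_max <- floor((geom$end - geom$start + .loc_eps) / geom$interval)
  geom$start + geom$interval * (0:k_max)
}

#' Match simulated to real slice positions
#'
#' Greedy nearest-neighbour pairing of two ascending position lists: candidate
#' pairs are considered in order of increasing |delta z|, each index on either
#' side is used at most once, and pairs farther apart than `tol` are dropped.
#' Needed to evaluate a simulated thick series against a real (or oracle) one
#' whose grid may be offset or have a different slice count.
#'
#' @param simulated,real Ascending numeric vectors of slice-center z (mm).
#' @param tol Maximum |delta z| (mm) for a pair to count as matched.
#' @return A tibble with columns `sim_index`, `real_index` (1-based),
#'   `sim_z`, `real_z`, `dz`, ordered by `sim_index`; attributes
#'   `unmatched_sim` and `unmatched_real` carry the leftover counts.
#' @export
match_positions <- function(simulated, real, tol) {
  simulated <- as.numeric(simulated); real <- as.numeric(real)
  stopifnot(tol >= 0)
  empty <- tibble::tibble(sim_index = integer(), real_index = integer(),
                          sim_z = numeric(), real_z = numeric(), dz = numeric())
  if (length(simulated) == 0L || length(real) == 0L) {
    attr(empty, "unmatched_sim") <- length(simulated)
    attr(empty, "unmatched_real") <- length(real)
    return(empty)
  }
  dz <- abs(outer(simulated, real, "-"))
  cand <- which(dz <= tol, arr.ind = TRUE)
  out <- empty
  if (nrow(cand) > 0L) {
    cand <- cand[order(dz[cand]), , drop = FALSE]
    used_sim <- logical(length(simulated)); used_real <- logical(length(real))
    keep_sim <- integer(0); keep_real <- integer(0)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1L]; j <- cand[r, 2L]
      if (!used_sim[i] && !used_real[j]) {
        used_sim[i] <- TRUE; used_real[j] <- TRUE
        keep_sim <- c(keep_sim, i); keep_real <- c(keep_real, j)
      }
    }
    ord <- order(keep_sim)
    keep_sim <- unname(keep_sim[ord]); keep_real <- unname(keep_real[ord])
    out <- tibble::tibble(
      sim_index = keep_sim, real_index = keep_real,
      sim_z = simulated[keep_sim], real_z = real[keep_real],
      dz = simulated[keep_sim] - real[keep_real]
    )
  }
  attr(out, "unmatched_sim") <- length(simulated) - nrow(out)
  attr(out, "unmatched_real") <- length(real) - nrow(out)
  out
}
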