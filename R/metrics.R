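#' Mean squared error between two slices
#'
#' `MSE = mean((ref - test)^2)` over all `m x n` pixels.
#'
#' @param ref,test Numeric matrices of identical shape.
#' @return Non-negative scalar.
#' @export
mse <- function(ref, test) {
  .check_pair(ref, test)
  mean((ref - test)^2)
}

#' Root mean squared error between two slices
#'
#' @inheritParams mse
#' @return `sqrt(mse(ref, test))`.
#' @export
rmse <- function(ref, test) sqrt(mse(ref, test))

#' Peak signal-to-noise ratio between two slices
#'
#' `PSNR = 20 * log10(max_i / sqrt(MSE))` in dB, where `max_i` is the maximum
#' possible pixel value on the intensity scale in use (1 for unit-normalised
#' intensities). Returns `Inf` when the slices are identical (`MSE = 0`).
#'
#' @inheritParams mse
#' @param max_i Maximum possible pixel value (`> 0`).
#' @return PSNR in dB (`Inf` for a zero-error pair).
#' @export
psnr <- function(ref, test, max_i = 1) {
  if (length(max_i) != 1L || !is.finite(max_i) || max_i <= 0) {
    stop("`max_i` must be a single positive number", call. = FALSE)
  }
  m <- mse(ref, test)
  if (m == 0) return(Inf)
  20 * log10(max_i / sqrt(m))
}

#' Structural similarity between two slices
#'
#' Mean local SSIM with the reference parameterisation: 11 x 11 Gaussian
#' window with sigma 1.5, stabilising constants `K1 = 0.01`, `K2 = 0.03` on a
#' unit dynamic range. Both slices are first clipped to the HU `window` and
#' mapped linearly to `[0, 1]`; local statistics use Gaussian-weighted sample
#' moments and the map is averaged over all valid (fully overlapping) window
#' placements. Constant inputs are handled by the stabilising constants —
#' identical constants give exactly 1.
#'
#' @inheritParams mse
#' @param window Length-2 numeric `(lo, hi)` HU normalisation window.
#' @return Scalar in `[-1, 1]`.
#' @export
ssim <- function(ref, test, window = c(-1024, 3071)) {
  .check_pair(ref, test)
  .check_window(window)
  if (any(dim(ref) < 11L)) {
    stop("slices must be at least 11 x 11 for the 11 x 11 SSIM window", call. = FALSE)
  }
  x <- normalize_window(ref, window)
  y <- normalize_window(test, window)
  k <- dnorm(seq.int(-5L, 5L), sd = 1.5)
  k <- k / sum(k)
  C1 <- 0.01^2
  C2 <- 0.03^2
  f <- function(m) .conv2_valid(m, k)
  mu_x <- f(x); mu_y <- f(y)
  sxx <- f(x * x) - mu_x^2
  syy <- f(y * y) - mu_y^2
  sxy <- f(x * y) - mu_x * mu_y
  num <- (2 * mu_x * mu_y + C1) * (2 * sxy + C2)
  den <- (mu_x^2 + mu_y^2 + C1) * (sxx + syy + C2)
  mean(num / den)
}

# separable 'valid' 2D convolution with a symmetric 1D kernel
.conv2_valid <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  n_out_r <- nrow(m) - 2L * r
  n_out_c <- ncol(m) - 2L * r
  Kr <- matrix(0, nrow = n_out_r, ncol = nrow(m))
  Kr[cbind(rep(seq_len(n_out_r), each = length(k)),
           as.vector(outer(seq_along(k), seq_len(n_out_r) - 1L, "+")))] <-
    rep(k, times = n_out_r)
  Kc <- matrix(0, nrow = n_out_c, ncol = ncol(m))
  Kc[cbind(rep(seq_len(n_out_c), each = length(k)),
           as.vector(outer(seq_along(k), seq_len(n_out_c) - 1L, "+")))] <-
    rep(k, times = n_out_c)
  Kr %*% m %*% t(Kc)
}

#' Clip to an HU window and rescale to \[0, 1\]
#'
#' @param x Numeric array or matrix in HU.
#' @param window Length-2 `(lo, hi)` HU bounds.
#' @return `x` clipped to `window` and mapped linearly to `[0, 1]`.
#' @export
normalize_window <- function(x, window = c(-1024, 3071)) {
  .check_window(window)
  (pmin(pmax(x, window[1L]), window[2L]) - window[1L]) / (window[2L] - window[1L])
}

#' Compare a simulated against a reference volume
#'
#' Matches slices by physical position ([match_positions()]), normalises both
#' volumes to `[0, 1]` over the HU `window` (so `max_i = 1`), computes
#' PSNR/MSE/RMSE/SSIM per matched slice pair and aggregates as
#' mean +/- standard deviation. Unmatched slices on either side are counted
#' and excluded from the aggregates. Pairs with zero error contribute an
#' infinite PSNR; aggregate PSNR statistics are taken over the finite pairs
#' and the infinite count is reported.
#'
#' @param sim,ref [axial_volume()]s sharing in-plane shape; `ref` is the
#'   reference (ground truth).
#' @param tol Position-matching tolerance in mm.
#' @param window Length-2 `(lo, hi)` HU normalisation window.
#' @return A `metric_report`: list with `per_slice` (tibble: one row per
#'   matched pair), `aggregate` (tibble: mean/sd per metric), `window`,
#'   `max_i`, `n_matched`, `unmatched_sim`, `unmatched_ref`.
#' @export
evaluate_volumes <- function(sim, ref, tol = 0.5, window = c(-1024, 3071)) {
  stopifnot(inherits(sim, "axial_volume"), inherits(ref, "axial_volume"))
  if (!identical(dim(sim$voxels)[1:2], dim(ref$voxels)[1:2])) {
    stop("volumes differ in in-plane shape", call. = FALSE)
  }
  pairs <- match_positions(sim$positions, ref$positions, tol)
  if (nrow(pairs) == 0L) {
    stop("no slice pairs matched within tolerance ", tol, " mm", call. = FALSE)
  }
  per <- lapply(seq_len(nrow(pairs)), function(r) {
    s <- normalize_window(get_slice(sim, pairs$sim_index[r]), window)
    g <- normalize_window(get_slice(ref, pairs$real_index[r]), window)
    m <- mse(g, s)
    tibble::tibble(
      sim_index = pairs$sim_index[r], ref_index = pairs$real_index[r],
      sim_z = pairs$sim_z[r], ref_z = pairs$real_z[r],
      mse = m, rmse = sqrt(m),
      psnr = if (m == 0) Inf else 20 * log10(1 / sqrt(m)),
      ssim = if (all(dim(s) >= 11L)) {
        ssim(get_slice(ref, pairs$real_index[r]),
             get_slice(sim, pairs$sim_index[r]), window)
      } else NA_real_
    )
  })
  per <- do.call(rbind, per)
  agg <- do.call(rbind, lapply(c("psnr", "mse", "rmse", "ssim"), function(nm) {
    v <- per[[nm]]
    fin <- v[is.finite(v)]
    tibble::tibble(metric = nm,
                   mean = if (length(fin)) mean(fin) else NA_real_,
                   sd = if (length(fin) > 1L) sd(fin) else NA_real_,
                   n_finite = length(fin), n_infinite = sum(is.infinite(v)))
  }))
  structure(
    list(per_slice = per, aggregate = agg, window = window, max_i = 1,
         n_matched = nrow(per),
         unmatched_sim = attr(pairs, "unmatched_sim"),
         unmatched_ref = attr(pairs, "unmatched_real")),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %d matched slice pair%s (%d/%d unmatched sim/ref)\n",
              x$n_matched, if (x$n_matched == 1L) "" else "s",
              x$unmatched_sim, x$unmatched_ref))
  cat(sprintf("  HU window [%g, %g], max_i = %g\n",
              x$window[1L], x$window[2L], x$max_i))
  print(x$aggregate)
  invisible(x)
}

#' Per-slice metric table of a metric report
#'
#' @param x A `metric_report` from [evaluate_volumes()].
#' @param ... Unused.
#' @return Tibble with one row per matched slice pair.
#' @method tidy metric_report
#' @export
tidy.metric_report <- function(x, ...) x$per_slice

#' One-row summary of a metric report
#'
#' @inheritParams tidy.metric_report
#' @return One-row tibble with mean/sd per metric and match counts.
#' @method glance metric_report
#' @export
glance.metric_report <- function(x, ...) {
  wide <- stats::setNames(
    as.list(c(rbind(x$aggregate$mean, x$aggregate$sd))),
    as.vector(rbind(paste0(x$aggregate$metric, "_mean"),
                    paste0(x$aggregate$metric, "_sd"))))
  tibble::as_tibble(c(wide, list(
    n_matched = x$n_matched, unmatched_sim = x$unmatched_sim,
    unmatched_ref = x$unmatched_ref,
    window_lo = x$window[1L], window_hi = x$window[2L], max_i = x$max_i)))
}

#' Plot per-slice fidelity metrics along the volume
#'
#' @param object A `metric_report`.
#' @param metrics Character vector of metrics to show.
#' @param ... Unused.
#' @return A ggplot: metric value against slice z-position, one panel per metric.
#' @method autoplot metric_report
#' @export
autoplot.metric_report <- function(object, metrics = c("psnr", "rmse", "ssim"), ...) {
  per <- object$per_slice
  long <- do.call(rbind, lapply(metrics, function(nm) {
    tibble::tibble(z = per$ref_z, metric = nm, value = per[[nm]])
  }))
  long <- long[is.finite(long$value), , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$z, y = .data$value)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "slice position z (mm)", y = NULL,
                  title = "Per-slice fidelity vs reference")
}

.check_pair <- function(ref, test) {
  if (!is.matrix(ref) || !is.matrix(test)) {
    stop("slices must be numeric matrices", call. = FALSE)
  }
  if (!identical(dim(ref), dim(test))) {
    stop("slice shapes differ: ", paste(dim(ref), collapse = "x"),
         " vs ", paste(dim(test), collapse = "x"), call. = FALSE)
  }
}

.check_window <- function(window) {
  if (length(window) != 2L || any(!is.finite(window)) || window[2L] <= window[1L]) {
    stop("`window` must be (lo, hi) with hi > lo", call. = FALSE)
  }
}
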