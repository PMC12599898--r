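# Independent brute-force oracles. These deliberately mirror the procedural
# definitions (while-loops, per-voxel accumulation) rather than the vectorised
# implementation paths they check.

# slice placement by literal repeated addition: p <- s; while (s <= p <= e)
loc_oracle <- function(s, e, d, eps = 1e-6) {
  out <- numeric(0)
  p <- s
  while (p >= s - eps && p <= e + eps) {
    out <- c(out, p)
    p <- p + d
  }
  out
}

# literal per-location, per-slice, per-voxel weighted-sum transcription
simulate_proposed_naive <- function(thin, geom) {
  targets <- slice_locations(geom)
  t <- geom$thickness
  d <- dim(thin$voxels)
  out <- array(0, dim = c(d[1L], d[2L], length(targets)))
  for (k in seq_along(targets)) {
    l <- targets[k]
    acc <- matrix(0, d[1L], d[2L])
    w_total <- 0
    for (i in seq_len(d[3L])) {
      w <- max(0, 1 - abs(targets[k] - thin$positions[i]) / t)
      if (w == 0) next
      acc <- acc + thin$voxels[, , i] * w
      w_total <- w_total + w
    }
    out[, , k] <- acc / w_total
  }
  axial_volume(out, positions = targets, thickness = t, spacing = thin$spacing)
}

# random thin volume on a uniform grid
rand_volume <- function(seed, rows = 16L, cols = 16L, n = 40L,
                        z0 = 0, dz = 1, thickness = dz) {
  set.seed(seed)
  axial_volume(array(rnorm(rows * cols * n, mean = 50, sd = 200),
                     dim = c(rows, cols, n)),
               positions = z0 + (seq_len(n) - 1L) * dz,
               thickness = thickness)
}

# constant-valued volume
const_volume <- function(value, rows = 8L, cols = 8L, n = 6L, dz = 1,
                         thickness = dz) {
  axial_volume(array(value, dim = c(rows, cols, n)),
               positions = (seq_len(n) - 1L) * dz, thickness = thickness)
}

# volume whose voxel values are affine in slice position: a + b * z
ramp_volume <- function(a = 0, b = 10, rows = 8L, cols = 8L, n = 11L, dz = 1,
                        thickness = dz) {
  pos <- (seq_len(n) - 1L) * dz
  vox <- array(rep(a + b * pos, each = rows * cols), dim = c(rows, cols, n))
  axial_volume(vox, positions = pos, thickness = thickness)
}

# direct textbook SSIM on a single patch with uniform weights (for sign checks)
ssim_patch_oracle <- function(x, y, C1 = 0.01^2, C2 = 0.03^2) {
  mx <- mean(x); my <- mean(y)
  vx <- mean(x^2) - mx^2; vy <- mean(y^2) - my^2
  cxy <- mean(x * y) - mx * my
  ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

python_bin <- function() Sys.which("python")
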