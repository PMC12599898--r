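test_that("triangular weight reproduces its closed form", {
  expect_identical(triangular_weight(3, 3, 2), 1)
  expect_identical(triangular_weight(0, 2, 2), 0)
  expect_equal(triangular_weight(1.5, 1.0, 2.0), 0.75)
  expect_error(triangular_weight(0, 0, 0), "positive")
  expect_error(triangular_weight(0, 0, -1), "positive")

  set.seed(7)
  p <- runif(500, -50, 50); l <- runif(500, -50, 50); t <- runif(500, 0.1, 10)
  for (i in seq_len(500)) {
    w <- triangular_weight(p[i], l[i], t[i])
    expect_equal(w, max(0, 1 - abs(p[i] - l[i]) / t[i]))
    expect_equal(w, triangular_weight(l[i], p[i], t[i]))  # symmetry
    expect_true(w >= 0 && w <= 1)
  }
  expect_equal(triangular_weight(c(0, 1, 2), 1, 1), c(0, 1, 0))
})

test_that("proposed simulator matches hand-evaluated weighted sums", {
  rows <- 4L; cols <- 4L
  vox <- array(0, dim = c(rows, cols, 3))
  vox[, , 2] <- 10; vox[, , 3] <- 20
  thin <- axial_volume(vox, positions = c(0, 1, 2), thickness = 1)

  # t = 1 at p = 1: weights (0, 1, 0) -> exactly the middle slice
  out <- simulate_proposed(thin, slice_geometry(1, 1, 1, 1))
  expect_identical(out$voxels[, , 1], thin$voxels[, , 2])

  # t = 2 at p = 1: weights (0.5, 1, 0.5) -> (0*0.5 + 10*1 + 20*0.5)/2 = 10
  out <- simulate_proposed(thin, slice_geometry(1, 1, 1, 2))
  expect_equal(out$voxels[, , 1], matrix(10, rows, cols))

  # constant volume stays constant for any target in range
  cv <- const_volume(37, n = 3L)
  out <- simulate_proposed(cv, slice_geometry(0.3, 1.7, 0.7, 2))
  expect_equal(out$voxels, array(37, dim = dim(out$voxels)))
})

test_that("proposed output carries the target geometry", {
  thin <- rand_volume(1, n = 21L)
  g <- slice_geometry(0, 20, 2, 3)
  out <- simulate_proposed(thin, g)
  expect_equal(out$positions, seq(0, 20, by = 2))
  expect_equal(out$thickness, 3)
  expect_equal(dim(out$voxels)[1:2], dim(thin$voxels)[1:2])
})

test_that("thin-coverage gaps wider than the thickness are a hard error", {
  vox <- array(0, dim = c(4, 4, 4))
  thin <- axial_volume(vox, positions = c(0, 1, 9, 10), thickness = 1)
  expect_error(simulate_proposed(thin, slice_geometry(0, 10, 5, 1)), "gap")
})

test_that("vectorised proposed simulator equals the naive triple-loop oracle", {
  set.seed(11)
  for (rep in 1:5) {
    thin <- rand_volume(100 + rep, rows = 16L, cols = 16L, n = 40L)
    s <- runif(1, 0, 5); e <- runif(1, 25, 39)
    g <- slice_geometry(s, e, runif(1, 0.5, 4), runif(1, 0.5, 5))
    fast <- simulate_proposed(thin, g)
    slow <- simulate_proposed_naive(thin, g)
    expect_lt(max(abs(fast$voxels - slow$voxels)), 1e-9)
    expect_equal(fast$positions, slow$positions)
  }
})

test_that("proposed output voxels stay inside the contributing envelope", {
  set.seed(5)
  thin <- rand_volume(5, rows = 8L, cols = 8L, n = 20L)
  g <- slice_geometry(0.5, 18.5, 1.5, 2.5)
  out <- simulate_proposed(thin, g)
  for (k in seq_along(out$positions)) {
    w <- triangular_weight(out$positions[k], thin$positions, g$thickness)
    contrib <- which(w > 0)
    lo <- apply(thin$voxels[, , contrib, drop = FALSE], c(1, 2), min)
    hi <- apply(thin$voxels[, , contrib, drop = FALSE], c(1, 2), max)
    expect_true(all(out$voxels[, , k] >= lo - 1e-9))
    expect_true(all(out$voxels[, , k] <= hi + 1e-9))
  }
})

test_that("identity limit: small thickness at a thin position returns that slice", {
  thin <- rand_volume(9, n = 10L)
  out <- simulate_proposed(thin, slice_geometry(4, 4, 1, 1))
  expect_identical(out$voxels[, , 1], thin$voxels[, , 5])
})

test_that("affine-in-z volumes are reproduced exactly at any target position", {
  thin <- ramp_volume(a = -30, b = 7.5, n = 21L)
  g <- slice_geometry(2.5, 17.5, 1.25, 2)   # kernel support fully covered
  out <- simulate_proposed(thin, g)
  for (k in seq_along(out$positions)) {
    expect_equal(out$voxels[, , k],
                 matrix(-30 + 7.5 * out$positions[k], 8, 8),
                 tolerance = 1e-9)
  }
})

test_that("direct downsampling keeps every factor-th slice with its position", {
  thin <- rand_volume(2, n = 6L)
  out <- simulate_direct_downsample(thin, 3)
  expect_equal(out$positions, thin$positions[c(1, 4)])
  expect_identical(out$voxels, thin$voxels[, , c(1, 4)])
  expect_equal(out$thickness, 3 * thin$thickness)

  out <- simulate_direct_downsample(thin, 1)
  expect_identical(out$voxels, thin$voxels)

  thin5 <- rand_volume(3, n = 5L)
  out <- simulate_direct_downsample(thin5, 2)
  expect_equal(out$positions, thin5$positions[c(1, 3, 5)])
  expect_error(simulate_direct_downsample(thin, 0), "factor")
})

test_that("simple averaging groups consecutive slices and drops the remainder", {
  vox <- array(0, dim = c(4, 4, 2)); vox[, , 2] <- 2
  thin <- axial_volume(vox, positions = c(0, 1), thickness = 1)
  out <- simulate_simple_average(thin, 2)
  expect_equal(out$voxels[, , 1], matrix(1, 4, 4))
  expect_equal(out$positions, 0.5)
  expect_equal(out$thickness, 2)

  thin7 <- rand_volume(4, n = 7L)
  out <- simulate_simple_average(thin7, 3)
  expect_equal(dim(out$voxels)[3], 2L)
  expect_equal(out$voxels[, , 1],
               (thin7$voxels[, , 1] + thin7$voxels[, , 2] + thin7$voxels[, , 3]) / 3)
  expect_equal(out$positions, c(1, 4))

  cv <- const_volume(12, n = 9L)
  out <- simulate_simple_average(cv, 4)
  expect_equal(out$voxels, array(12, dim = dim(out$voxels)))
  expect_error(simulate_simple_average(rand_volume(1, n = 2L), 3), "smaller")
})

test_that("gaussian averaging preserves constants and reduces to its kernel", {
  cv <- const_volume(55, n = 12L)
  out <- simulate_gaussian_average(cv, sigma = 1.3, factor = 2)
  expect_equal(out$voxels, array(55, dim = dim(out$voxels)), tolerance = 1e-12)

  # impulse response equals the normalized kernel (away from the edge
  # renormalisation zone, factor 1)
  n <- 31L; mid <- 16L
  vox <- array(0, dim = c(4, 4, n)); vox[, , mid] <- 1
  thin <- axial_volume(vox, positions = seq_len(n), thickness = 1)
  sigma <- 1.5
  out <- simulate_gaussian_average(thin, sigma = sigma, factor = 1)
  r <- ceiling(4 * sigma)
  kern <- dnorm(seq.int(-r, r), sd = sigma); kern <- kern / sum(kern)
  profile <- out$voxels[1, 1, ]
  expect_equal(profile[(mid - r):(mid + r)], kern, tolerance = 1e-12)
  expect_true(all(profile[c(1:(mid - r - 1), (mid + r + 1):n)] == 0))

  # sigma -> 0+ collapses to direct downsampling
  thin <- rand_volume(8, n = 10L)
  out <- simulate_gaussian_average(thin, sigma = 1e-9, factor = 2)
  ref <- simulate_direct_downsample(thin, 2)
  expect_equal(out$voxels, ref$voxels, tolerance = 1e-12)
  expect_error(simulate_gaussian_average(thin, sigma = 0, factor = 2), "sigma")
})

test_that("difference maps equal elementwise subtraction", {
  a <- rand_volume(21, rows = 6L, cols = 6L, n = 5L)
  b <- rand_volume(22, rows = 6L, cols = 6L, n = 5L)
  dm <- difference_map(a, b)
  # direct loop subtraction oracle
  for (k in 1:5) {
    expect_equal(dm$voxels[, , k], a$voxels[, , k] - b$voxels[, , k])
  }
  expect_equal(difference_map(a, a)$voxels, array(0, dim = dim(a$voxels)))
  ca <- const_volume(5); cb <- const_volume(2)
  expect_equal(difference_map(ca, cb)$voxels, array(3, dim = dim(ca$voxels)))
  shifted <- axial_volume(b$voxels, positions = b$positions + 1,
                          thickness = b$thickness)
  expect_error(difference_map(a, shifted), "positions")
  small <- rand_volume(23, rows = 4L, cols = 6L, n = 5L)
  expect_error(difference_map(a, small), "shape")
})

test_that("index-based baselines misplace slices where the proposed method does not", {
  # thin series 0..10 mm at 1 mm; target 2 mm interval
  thin <- rand_volume(31, n = 11L)
  prop <- simulate_proposed(thin, slice_geometry(0, 10, 2, 2))
  expect_equal(prop$positions, seq(0, 10, by = 2))

  # simple averaging with factor 2 puts slices at group means (0.5, 2.5, ...):
  # off the true 2 mm grid by half the thin spacing
  avg <- simulate_simple_average(thin, 2)
  expect_equal(avg$positions, seq(0.5, 8.5, by = 2))
  expect_gt(min(abs(outer(avg$positions, prop$positions, "-"))), 0.4)

  # direct downsampling reuses thin positions: on-grid here, but the slice
  # count disagrees with the physical extent once the parity flips
  thin12 <- rand_volume(32, n = 12L)
  dd <- simulate_direct_downsample(thin12, 2)
  prop12 <- simulate_proposed(thin12, slice_geometry(0, 11, 2, 2))
  expect_equal(length(prop12$positions), 6L)
  expect_equal(dd$positions, seq(0, 10, by = 2))
})

test_that("simulate_thick dispatches on method name", {
  thin <- rand_volume(41, n = 8L)
  expect_equal(simulate_thick(thin, "direct_downsample", factor = 2)$voxels,
               simulate_direct_downsample(thin, 2)$voxels)
  expect_error(simulate_thick(thin, "proposed"), "geom")
  expect_error(simulate_thick(thin, "no_such_method"))
})
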