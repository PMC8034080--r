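# Postprocessing: median smoothing, connectivity, ellipsoid fitting,
# vesselness scoring, and false-negative recovery.

test_that("3D median preserves bulk and removes isolated voxels", {
  cube <- array(FALSE, c(16, 16, 16))
  cube[4:13, 4:13, 4:13] <- TRUE
  out <- median3d(binary_volume(cube), 2)
  # cube preserved up to corner rounding: every removed voxel is near an
  # edge or corner (close to at least two faces), and the bulk survives
  expect_gt(sum(out$data), 0.85 * sum(cube))
  expect_lte(sum(out$data), sum(cube))
  expect_true(all(cube[out$data]))
  removed <- which(cube & !out$data, arr.ind = TRUE)
  near_face <- abs(removed - 4) <= 1 | abs(removed - 13) <= 1
  expect_true(all(rowSums(near_face) >= 2))
  lone <- array(FALSE, c(9, 9, 9))
  lone[5, 5, 5] <- TRUE
  expect_false(any(median3d(binary_volume(lone), 3)$data))
  # kernel 0 is the identity
  expect_identical(median3d(binary_volume(cube), 0)$data, cube)
  expect_error(median3d(binary_volume(cube), 20), "larger")
})

test_that("split_connected joins top-touching parts through the virtual slice", {
  m <- array(FALSE, c(20, 20, 20))
  m[5, 5, 1:20] <- TRUE    # bar touching the top
  m[15, 15, 1:20] <- TRUE  # second bar touching the top
  parts <- split_connected(binary_volume(m))
  expect_true(all(parts$largest$data[m]))
  expect_equal(parts$n_others, 0L)
  # floating blob lands in `others`
  m2 <- m
  m2[10:12, 10:12, 10:12] <- TRUE
  parts <- split_connected(binary_volume(m2))
  expect_equal(parts$n_others, 1L)
  expect_false(any(parts$largest$data[10:12, 10:12, 10:12]))
  expect_true(all(parts$others[10:12, 10:12, 10:12] == 1L))
  # bounded-ROI virtual slice: a blob outside the ROI at the top is not
  # bridged into the root system
  roi <- interpolate_roi(circle_roi(1, 10, 10, 6), circle_roi(10, 10, 10, 6),
                         circle_roi(20, 10, 10, 6), 20)
  m3 <- array(FALSE, c(20, 20, 20))
  m3[10, 10, 1:20] <- TRUE   # inside ROI, touches top
  m3[19, 19, 1:3] <- TRUE    # outside ROI, touches top
  parts <- split_connected(binary_volume(m3), roi)
  expect_false(any(parts$largest$data[19, 19, ]))
  expect_equal(parts$n_others, 1L)
  expect_error(split_connected(binary_volume(array(FALSE, c(4, 4, 4)))),
               "empty")
})

test_that("ellipsoid fits agree with moment oracles", {
  # digitized solid sphere r = 10: lambda ~ (10, 10, 10) within 5%
  g <- as.matrix(expand.grid(x = 1:21, y = 1:21, z = 1:21))
  sphere <- g[sqrt(rowSums((g - 11)^2)) <= 10, ]
  lam <- fit_ellipsoid(sphere)
  expect_true(all(abs(lam - 10) / 10 < 0.05))
  # solid axis-aligned cylinder r = 3, length 60: lambda3 ~ sqrt(5/12) * 60
  g <- as.matrix(expand.grid(x = 1:9, y = 1:9, z = 1:60))
  cyl <- g[sqrt((g[, 1] - 5)^2 + (g[, 2] - 5)^2) <= 3, ]
  lam <- fit_ellipsoid(cyl)
  expect_lt(abs(lam[3] - sqrt(5 / 12) * 60) / (sqrt(5 / 12) * 60), 0.05)
  expect_lt(abs(lam[1] - 3) / 3, 0.2)
  # independent covariance eigen-oracle on the same voxel set
  cc <- scale(cyl, scale = FALSE)
  ev <- sort(eigen(crossprod(cc) / nrow(cyl))$values)
  expect_equal(unname(lam), unname(sqrt(5 * ev)), tolerance = 1e-8)
  # degenerate: single voxel floored at half a voxel
  expect_equal(fit_ellipsoid(matrix(c(3, 4, 5), 1)), c(0.5, 0.5, 0.5))
  # array input
  a <- array(FALSE, c(9, 9, 9)); a[3:7, 4, 5] <- TRUE
  expect_equal(fit_ellipsoid(a)[3], sqrt(5 * 2), tolerance = 1e-8)
})

test_that("vesselness scores match the closed form", {
  s <- vesselness_score(1, 1, 1)
  expect_equal(s$Rb, 1)
  expect_equal(s$Ra, 1)
  expect_equal(s$nu, exp(-2))
  long_cyl <- vesselness_score(1, 1, 100)
  expect_equal(long_cyl$Rb, 0.1)
  expect_equal(long_cyl$Ra, 0.01)
  expect_equal(long_cyl$nu, exp(-0.01) * exp(-1e-4))
  expect_gt(long_cyl$nu, 0.98)
  plate <- vesselness_score(0.1, 10, 10)
  expect_equal(plate$nu, exp(-1e-4) * exp(-1), tolerance = 1e-6)
  expect_lt(plate$nu, 0.85)  # plates rejected at t_v
  expect_error(vesselness_score(3, 2, 1), "sorted")
  expect_error(vesselness_score(0, 1, 2), "positive")
})

test_that("vesselness is scale-invariant and decreasing in both ratios", {
  set.seed(17)
  for (i in 1:20) {
    lam <- sort(runif(3, 0.5, 30))
    s <- vesselness_score(lam[1], lam[2], lam[3])
    f <- runif(1, 0.1, 10)
    s2 <- vesselness_score(f * lam[1], f * lam[2], f * lam[3])
    expect_equal(s$nu, s2$nu, tolerance = 1e-12)
  }
  # strictly decreasing in Rb and Ra
  nu_of <- function(Rb, Ra) exp(-Rb^2) * exp(-Ra^2)
  rb <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(nu_of(rb, 0.5)) < 0))
  expect_true(all(diff(nu_of(0.5, rb)) < 0))
})

test_that("false-negative recovery keeps cylinder-like objects only", {
  base <- array(FALSE, c(64, 64, 64))
  base[32, 32, 1:64] <- TRUE   # connected root system
  others <- array(0L, c(64, 64, 64))
  # detached straight segment ~ (2, 2, 40)-ish: recovered
  others[10:13, 10:13, 5:60] <- 1L
  # sphere r = 6: discarded by vesselness
  g <- expand.grid(x = 1:13, y = 1:13, z = 1:13)
  sph <- sqrt((g$x - 7)^2 + (g$y - 7)^2 + (g$z - 7)^2) <= 6
  others[40:52, 40:52, 30:42][as.matrix(g[sph, ])] <- 2L
  # short elongated object lambda3 < 25: discarded by size
  others[50:52, 20:22, 5:15] <- 3L
  rec <- recover_false_negatives(binary_volume(base), others,
                                 t_v = 0.85, t_s = 25)
  expect_equal(rec$shapes$recovered, c(TRUE, FALSE, FALSE))
  expect_gt(rec$shapes$nu[1], 0.85)
  expect_gt(rec$shapes$lambda3[1], 25)
  expect_lt(rec$shapes$nu[2], 0.5)
  expect_lt(rec$shapes$lambda3[3], 25)
  # final mask = largest plus recovered objects only
  expect_true(all(rec$mask$data[base]))
  expect_true(all(rec$mask$data[others == 1L]))
  expect_false(any(rec$mask$data[others == 2L]))
  expect_false(any(rec$mask$data[others == 3L]))
  # the worked example: lambda = (2, 2, 40) passes both criteria
  s <- vesselness_score(2, 2, 40)
  expect_equal(s$nu, exp(-(2 / sqrt(80))^2) * exp(-0.05^2))
  expect_gt(s$nu, 0.85)
})
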