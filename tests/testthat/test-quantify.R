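# Skeletonization, local thickness, diameter distributions, and the
# recovery regression.

test_that("skeleton length matches straight and diagonal cylinders", {
  # straight axis-aligned cylinder, 100 voxels, d = 6
  mask <- make_cylinder_mask(6, 100)
  skel <- skeletonize(mask)
  len_vox <- skel$total_length_um / 45
  expect_lte(abs(len_vox - 100), 3)
  # one straight branch
  expect_equal(nrow(skel$branches), 1L)
  # skeleton of a connected mask is connected
  lab <- rootct:::.label_cpp(as.logical(skel$mask$data), dim(skel$mask$data))
  expect_equal(max(lab), 1L)
  # 45-degree in-plane cylinder of axial extent 100: length ~ 100 sqrt(2)
  n <- 110
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:15)
  a <- c(5, 5, 8); b <- c(105, 105, 8)
  t <- pmin(pmax(((g$x - a[1]) + (g$y - a[2])) / 200, 0), 1)
  dist <- sqrt((g$x - (a[1] + 100 * t))^2 + (g$y - (a[2] + 100 * t))^2 +
               (g$z - 8)^2)
  m45 <- binary_volume(array(dist <= 3, c(n, n, 15)), 45)
  skel45 <- skeletonize(m45)
  expect_lt(abs(skel45$total_length_um / 45 - 100 * sqrt(2)) / (100 * sqrt(2)),
            0.05)
  # single voxel: zero length
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  sk1 <- skeletonize(binary_volume(one))
  expect_equal(sk1$total_length_um, 0)
  expect_equal(nrow(sk1$coords), 1L)
  expect_error(skeletonize(binary_volume(array(FALSE, c(4, 4, 4)))), "empty")
})

test_that("skeleton length is stable under median smoothing", {
  mask <- make_cylinder_mask(10, 80)
  l0 <- skeletonize(mask)$total_length_um
  l1 <- skeletonize(median3d(mask, 2))$total_length_um
  expect_lt(abs(l1 - l0) / l0, 0.02)
})

test_that("local thickness recovers sphere and cylinder diameters", {
  # solid sphere d = 11: central value 11 +- 1
  n <- 19
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  sph <- array(sqrt((g$x - 10)^2 + (g$y - 10)^2 + (g$z - 10)^2) <= 5.5,
               c(n, n, n))
  th <- local_thickness(binary_volume(sph))
  expect_lte(abs(th$data[10, 10, 10] - 11), 1)
  expect_true(all(th$data[!sph] == 0))
  # long cylinder d = 8: axis values 8 +- 1 away from the ends
  mask <- make_cylinder_mask(8, 60)
  th <- local_thickness(mask)
  c0 <- (dim(mask$data)[1] + 1) / 2
  axis_vals <- th$data[c0, c0, 10:50]
  expect_true(all(abs(axis_vals - 8) <= 1))
  # empty mask: all-zero map
  th0 <- local_thickness(binary_volume(array(FALSE, c(6, 6, 6))))
  expect_true(all(th0$data == 0))
})

test_that("diameter distribution assigns length to the right classes", {
  # single cylinder d = 8 voxels (360 um): one dominant class, RLD from
  # the known soil volume
  mask <- make_cylinder_mask(8, 100)
  skel <- skeletonize(mask)
  thick <- local_thickness(mask)
  dist <- diameter_distribution(skel, thick, soil_volume_cm3 = 1)
  expect_equal(sum(dist$length_cm), skel$total_length_um * 1e-4,
               tolerance = 0.01)
  dominant <- dist$diameter_vox[which.max(dist$length_cm)]
  expect_lte(abs(dominant - 8), 1)
  expect_equal(dist$rld_cm_per_cm3, dist$length_cm)
  # two cylinders d = 4 and d = 20: bimodal, modes at ~180 and ~900 um
  n <- 51
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:80)
  d1 <- sqrt((g$x - 13)^2 + (g$y - 13)^2)
  d2 <- sqrt((g$x - 36)^2 + (g$y - 36)^2)
  m <- binary_volume(array(d1 <= 2 | d2 <= 10, c(n, n, 80)), 45)
  skel <- skeletonize(m)
  dist <- diameter_distribution(skel, local_thickness(m), soil_volume_cm3 = 1)
  # fine mode within 1 class of 4 voxels (180 um), big within 1 of 20 (900)
  fine <- dist[dist$diameter_vox <= 10, ]
  big <- dist[dist$diameter_vox > 10, ]
  expect_lte(abs(fine$diameter_vox[which.max(fine$length_cm)] - 4), 1)
  expect_lte(abs(big$diameter_vox[which.max(big$length_cm)] - 20), 1)
  # per-class length within 10% of the true 80-voxel runs
  expect_lt(abs(sum(fine$length_cm) - 80 * 45e-4) / (80 * 45e-4), 0.10)
  expect_lt(abs(sum(big$length_cm) - 80 * 45e-4) / (80 * 45e-4), 0.10)
  # z-window restriction
  half <- diameter_distribution(skel, local_thickness(m), soil_volume_cm3 = 1,
                                z_range = c(1, 40))
  expect_lt(sum(half$length_cm), sum(dist$length_cm))
})

test_that("root recovery regression matches closed-form least squares", {
  expect_equal(root_recovery(c(1, 2, 3), c(1, 2, 3))$slope_origin, 1)
  expect_equal(root_recovery(c(1, 2, 3), c(1, 2, 3))$r_squared_free, 1)
  # exact proportionality: slope equals the factor
  ref <- c(0.5, 1.2, 2.0, 3.3)
  expect_equal(root_recovery(0.73 * ref, ref)$slope_origin, 0.73)
  # random pairs vs the normal equations
  set.seed(41)
  x <- runif(12, 0, 5); y <- 0.8 * x + rnorm(12, 0, 0.3)
  r <- root_recovery(y, x)
  expect_equal(r$slope_origin, sum(x * y) / sum(x^2))
  b <- cov(x, y) / var(x)
  expect_equal(r$slope_free, b)
  expect_equal(r$intercept_free, mean(y) - b * mean(x))
  expect_error(root_recovery(1, 1), "2 pairs")
})
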