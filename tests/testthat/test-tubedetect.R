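# Tubeness filtering, threshold calibration, the sigma schedule,
# hysteresis thresholding, and the multi-scale union.

test_that("tubeness responds on the cylinder axis with a concave transect", {
  cyl <- render_cylinder(8, shape = c(33, 33, 33))
  tb <- tubeness(cyl, 4)  # q = 0.5: concave regime
  prof <- rootct:::diametral_transect(tb)
  center <- rootct:::transect_at_radius(prof, 0)
  expect_equal(max(tb$data), 255)
  # single central maximum: the axis is the brightest point of the transect
  expect_equal(center, max(prof), tolerance = 0.01)
  expect_false(rootct:::transect_is_hollow(prof, 4))
  # low q: the filtered root appears hollow (two symmetric peaks)
  tb2 <- tubeness(cyl, 0.5)  # q = 0.0625
  prof2 <- rootct:::diametral_transect(tb2)
  expect_true(rootct:::transect_is_hollow(prof2, 4))
  # uniform volume: zero response, with a warning
  expect_warning(tb0 <- tubeness(gray_volume(array(80, c(16, 16, 16))), 2),
                 "zero")
  expect_true(all(tb0$data == 0))
})

test_that("tubeness is rotation-tolerant", {
  # d = 8 cylinder along x, y, z and an in-plane diagonal: raw axis
  # response within 10% across orientations
  d <- 8; sig <- 4
  resp_axis <- function(axis) {
    n <- 41
    g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
    c0 <- (n + 1) / 2
    dist <- switch(axis,
      z = sqrt((g$x - c0)^2 + (g$y - c0)^2),
      y = sqrt((g$x - c0)^2 + (g$z - c0)^2),
      x = sqrt((g$y - c0)^2 + (g$z - c0)^2),
      diag = {
        # axis along (1, 1, 0) / sqrt(2) through the center
        ux <- g$x - c0; uy <- g$y - c0; uz <- g$z - c0
        t <- (ux + uy) / 2
        sqrt((ux - t)^2 + (uy - t)^2 + uz^2)
      })
    vol <- gray_volume(array(round(pmin(pmax(d / 2 + 0.5 - dist, 0), 1) * 255),
                             c(n, n, n)))
    raw <- rootct:::.tubeness_cpp(as.double(vol$data), c(n, n, n), sig)
    max(raw)
  }
  vals <- vapply(c("x", "y", "z", "diag"), resp_axis, numeric(1))
  expect_lt((max(vals) - min(vals)) / max(vals), 0.10)
})

test_that("the calibration curve reproduces the published working point", {
  curve <- rootct:::cached_calibration(32, 96)
  # hollow regime excluded with a message, concave regime fitted
  expect_true(any(curve$points$hollow))
  expect_gte(curve$r_squared, 0.8)
  t_opt <- predict(curve, 0.5)
  expect_gte(t_opt, 74)
  expect_lte(t_opt, 84)
  # t_opt rises with q across the upper concave regime: more smoothing
  # spreads the normalized response, raising the value at the fixed root
  # outline (below q ~ 0.4 the outline response is essentially zero)
  conc <- curve$points[!curve$points$hollow & curve$points$q >= 0.4, ]
  expect_true(all(diff(conc$t_opt) > 0))
  low <- curve$points[!curve$points$hollow & curve$points$q < 0.4, ]
  expect_true(all(low$t_opt < 15))
  # q-normalization: a different cylinder diameter gives a similar curve
  curve2 <- calibrate_opt_threshold(d = 24, q_grid = c(0.375, 0.5, 0.75, 1),
                                    shape = 72)
  expect_lt(abs(predict(curve2, 0.5) - t_opt), 12)
  # all-hollow grid errors out
  expect_error(calibrate_opt_threshold(d = 32, q_grid = c(0.03125, 0.0625),
                                       shape = 64),
               "concave")
})

test_that("the sigma plan implements the diameter schedule", {
  plan <- build_sigma_plan(4, 4, 28, 8, 0.5, t_low = 79)
  expect_equal(plan$d_r, c(4, 8, 12, 16, 20, 24, 28))
  expect_equal(plan$f_s, c(1, 1, 0.5, 0.5, 0.5, 0.5, 0.5))
  # sigma = q * d * f_s exactly; a single-diameter plan at full
  # resolution gives sigma = q * d
  expect_equal(plan$sigma, plan$d_r * 0.5 * plan$f_s)
  expect_equal(build_sigma_plan(4, 4, 4, 4, 0.5, t_low = 79)$sigma, 2)
  expect_equal(plan$t_low, rep(79, 7))
  expect_error(build_sigma_plan(10, 4, 8, 9, 0.5, t_low = 79), "crossover")
})

test_that("hysteresis equals a flood-fill oracle", {
  # independent oracle: threshold at t_low, label components, keep those
  # containing a seed voxel
  flood_oracle <- function(v, t_low, t_high) {
    strong <- v$data >= t_high
    weak <- v$data >= t_low
    lab <- array(rootct:::.label_cpp(as.logical(weak), dim(v$data)),
                 dim(v$data))
    keep <- setdiff(unique(lab[strong]), 0L)
    array(lab %in% keep, dim(v$data))
  }
  for (seed in 1:5) {
    v <- random_volume(32, seed = seed)
    out <- hysteresis(v, 120, 220)
    expect_identical(out$data, flood_oracle(v, 120, 220))
  }
  # degenerate cases
  v <- random_volume(16, seed = 6)
  expect_identical(hysteresis(v, 200, 200)$data, v$data >= 200)
  none <- gray_volume(array(pmin(v$data, 150), dim(v$data)))
  expect_false(any(hysteresis(none, 100, 250)$data))
  expect_error(hysteresis(v, 250, 100), "t_low")
  # gradient bar: everything >= t_low connected to the bright end
  bar <- make_volume(32, 5, 5, function(x, y, z) round((x - 1) * 255 / 31))
  out <- hysteresis(bar, 100, 240)
  expect_identical(out$data, bar$data >= 100)
})

test_that("multi-scale union captures what single passes miss", {
  # two clean cylinders d = 4 and d = 24 in one volume
  n <- 64
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:48)
  d1 <- sqrt((g$x - 16)^2 + (g$y - 16)^2)
  d2 <- sqrt((g$x - 44)^2 + (g$y - 44)^2)
  cov <- pmax(pmin(pmax(2.5 - d1, 0), 1), pmin(pmax(12.5 - d2, 0), 1))
  vol <- gray_volume(array(round(cov * 255), c(n, n, 48)))
  plan <- build_sigma_plan(4, 20, 24, 8, 0.5, t_low = 79, t_high = 200)
  seg <- segment_roots(vol, plan)
  near_axis <- function(m, cx, cy) mean(m[cbind(cx, cy, 5:43)])
  # union captures both axes
  expect_gte(near_axis(seg$data, 16, 16), 0.9)
  expect_gte(near_axis(seg$data, 44, 44), 0.9)
  # neither single pass alone captures both
  p1 <- segment_roots(vol, plan[1, ])
  p2 <- segment_roots(vol, plan[2, ])
  expect_lt(near_axis(p1$data, 44, 44) * near_axis(p1$data, 16, 16), 0.5)
  expect_lt(near_axis(p2$data, 44, 44) * near_axis(p2$data, 16, 16), 0.5)
  # union is monotone: adding a pass never removes foreground
  expect_true(all(seg$data[p1$data]))
  expect_true(all(seg$data[p2$data]))
  # empty input stays empty
  empty <- gray_volume(array(0, c(24, 24, 24)))
  expect_warning(seg0 <- segment_roots(empty, plan[1, , drop = FALSE]))
  expect_false(any(seg0$data))
})

test_that("a matched pass recovers the cylinder diameter within one voxel", {
  # the central calibration claim: with sigma = q d f_s and the fitted
  # t_low, hysteresis recovers the original outline
  curve <- rootct:::cached_calibration(32, 96)
  t_low <- predict(curve, 0.5)
  d <- 12
  cyl <- render_cylinder(d, shape = c(41, 41, 41))
  tb <- tubeness(cyl, 0.5 * d)
  m <- hysteresis(tb, t_low, 200)
  th <- local_thickness(binary_volume(m$data, 45))
  mid <- th$data[21, 21, 21]
  expect_lte(abs(mid - d), 1)
})
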