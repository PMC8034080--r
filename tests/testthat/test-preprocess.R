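# Grayscale conditioning: stretch, stitch, attenuation, denoise, unsharp.

test_that("percentile stretch maps quantiles to 0/255 and stays monotone", {
  ramp <- make_volume(16, 4, 4, function(x, y, z) (x - 1) * 17)
  out <- percentile_stretch(ramp, 0)
  expect_equal(range(out$data), c(0, 255))
  # p = 0 on a 0..255 ramp is the identity
  ramp255 <- gray_volume(array(rep(0:255, length.out = 256), c(16, 4, 4)))
  expect_volumes_equal(percentile_stretch(ramp255, 0), ramp255)
  # quantile oracle on a mixed distribution: saturated tails map to 0/255
  # and interior values to their position between the stretch quantiles
  set.seed(11)
  vals <- c(rep(0, 10), round(runif(980, 40, 200)), rep(255, 10))
  v <- gray_volume(array(sample(vals), c(10, 10, 10)))
  out <- percentile_stretch(v, 0.02)
  q <- quantile(v$data, c(0.02, 0.98), names = FALSE)
  oracle <- round(pmin(pmax((v$data - q[1]) / (q[2] - q[1]) * 255, 0), 255))
  expect_equal(out$data, oracle)
  expect_true(all(out$data[v$data == 0] == 0))
  expect_true(all(out$data[v$data == 255] == 255))
  # monotone: ordering preserved on random data
  r <- random_volume(12, seed = 5)
  out <- percentile_stretch(r, 0.01)
  o <- order(as.vector(r$data))
  expect_true(all(diff(as.vector(out$data)[o]) >= 0))
  expect_error(percentile_stretch(gray_volume(array(9, c(4, 4, 4))), 0.002),
               "constant")
})

test_that("stitching removes the overlap exactly once", {
  bottom <- make_volume(4, 4, 10, function(x, y, z) z + 100)
  top <- make_volume(4, 4, 10, function(x, y, z) z)
  out <- stitch_stacks(bottom, top, 4)
  expect_equal(dim(out$data)[3], 16L)
  out0 <- stitch_stacks(bottom, top, 0)
  expect_equal(dim(out0$data)[3], 20L)
  expect_equal(out0$data[, , 1:10], top$data)
  expect_equal(out0$data[, , 11:20], bottom$data)
  # identical overlap region appears exactly once: top slices 9,10 ==
  # bottom slices 1,2 by construction here
  bottom2 <- make_volume(4, 4, 10, function(x, y, z) z + 8)
  out2 <- stitch_stacks(bottom2, top, 2)
  expect_equal(dim(out2$data)[3], 18L)
  expect_equal(as.vector(out2$data[1, 1, ]), as.numeric(1:18))
  expect_error(stitch_stacks(bottom, make_volume(5, 4, 10, function(x, y, z) z), 2),
               "mismatch")
})

test_that("attenuation correction equalizes per-slice statistics", {
  set.seed(21)
  # identical slices stay identical
  base <- array(rnorm(16 * 16, 100, 10), c(16, 16))
  vol <- gray_volume(array(rep(pmin(pmax(base, 0), 255), 5), c(16, 16, 5)))
  out <- attenuation_correct(vol, 3)
  expect_equal(out$data, vol$data, tolerance = 1e-10)
  # mu 50 sd 5 matched to mu 100 sd 10: a = 2, b = 0
  s1 <- rnorm(1000, 100, 10)
  s2 <- (s1 - 100) / 2 + 50  # exactly mu 50 sd 5 of the same shape
  vol <- gray_volume(array(c(s1, s2), c(10, 10, 20))[, , c(1:10, 11:20)])
  # per-slice step change: slices 1..10 from s1, 11..20 from s2
  out <- attenuation_correct(vol, 1)
  mus <- apply(out$data, 3, mean)
  sds <- apply(out$data, 3, sd)
  expect_true(all(abs(mus - mus[1]) < 1))
  expect_true(all(abs(sds - sds[1]) < 1))
  # flat slice left unchanged with a warning
  flat <- gray_volume(array(c(rnorm(100, 100, 5), rep(7, 100)), c(10, 10, 2)))
  expect_warning(out <- attenuation_correct(flat, 1), "unchanged")
  expect_true(all(out$data[, , 2] == 7))
  expect_error(attenuation_correct(gray_volume(array(5, c(4, 4, 3))), 1),
               "zero background")
})

test_that("NLM denoising reduces noise and preserves structure", {
  # noise-free constant volume is unchanged
  const <- gray_volume(array(100, c(12, 12, 12)))
  expect_volumes_equal(nlm_denoise(const), const)
  # flat noisy region: output sd strictly below input sd
  set.seed(31)
  noisy <- gray_volume(array(pmin(pmax(round(rnorm(16^3, 100, 15)), 0), 255),
                             c(16, 16, 16)))
  den <- nlm_denoise(noisy, t_con = 60)
  inner <- den$data[4:13, 4:13, 4:13]
  expect_lt(sd(inner), sd(noisy$data[4:13, 4:13, 4:13]))
  expect_lt(abs(mean(inner) - mean(noisy$data[4:13, 4:13, 4:13])), 2)
  # two-phase volume: phase means preserved within 2 GV
  two <- make_volume(16, 16, 16, function(x, y, z) ifelse(x <= 8, 60, 180))
  set.seed(32)
  two$data <- pmin(pmax(round(two$data + rnorm(length(two$data), 0, 10)), 0), 255)
  den <- nlm_denoise(two, t_con = 40)
  # compare phase interiors, away from the partial-volume boundary
  lo <- den$data[2:6, , ]; hi <- den$data[12:16, , ]
  expect_lt(abs(mean(lo) - 60), 2)
  expect_lt(abs(mean(hi) - 180), 2)
})

test_that("unsharp mask sharpens edges and leaves flat regions alone", {
  const <- gray_volume(array(120, c(10, 10, 10)))
  expect_volumes_equal(unsharp_mask(const, 1, 0.7), const)
  # step edge: mid-edge gradient strictly steeper, with overshoot flanks;
  # checked against a 1D convolution oracle along the step axis
  step <- make_volume(24, 9, 9, function(x, y, z) ifelse(x <= 12, 50, 200))
  out <- unsharp_mask(step, 1, 0.7)
  prof_in <- step$data[, 5, 5]
  prof_out <- out$data[, 5, 5]
  expect_gt(prof_out[13] - prof_out[12], prof_in[13] - prof_in[12])
  expect_lt(min(prof_out[8:12]), 50)     # undershoot on the dark side
  expect_gt(max(prof_out[13:18]), 200)   # overshoot on the bright side
  # 1D oracle: same formula computed with stats::filter on the profile
  radius <- as.integer(4 * 1 + 0.5)
  k <- exp(-0.5 * ((-radius):radius)^2)
  k <- k / sum(k)
  padded <- c(rep(50, radius), prof_in, rep(200, radius))
  g <- as.numeric(stats::filter(padded, k, sides = 2))[(radius + 1):(radius + 24)]
  oracle <- pmin(pmax((prof_in - 0.7 * g) / 0.3, 0), 255)
  expect_equal(prof_out[3:22], round(oracle)[3:22], tolerance = 1.01)
  # w -> 0 approaches the identity
  out_small <- unsharp_mask(step, 1, 1e-6)
  expect_true(max(abs(out_small$data - step$data)) <= 1)
  expect_error(unsharp_mask(step, 1, 1.2), "mask_weight")
})

test_that("the 16-bit offset round trip does not shift the gray scale", {
  set.seed(33)
  noisy <- gray_volume(array(pmin(pmax(round(rnorm(12^3, 80, 12)), 0), 255),
                             c(12, 12, 12)))
  # with a translation-invariant denoiser, any constant offset must cancel
  a <- nlm_denoise(noisy, t_con = 60, offset = 50000)
  b <- nlm_denoise(noisy, t_con = 60, offset = 0)
  expect_true(max(abs(a$data - b$data)) <= 1)
})
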