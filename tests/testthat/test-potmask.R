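# Pot-wall mask interpolation, masking, and histogram peak analysis.

test_that("ROI interpolation is piecewise linear through the anchors", {
  m <- interpolate_roi(circle_roi(1, 50, 50, 30), circle_roi(51, 50, 50, 30),
                       circle_roi(101, 50, 50, 30), 101)
  expect_true(all(m$circles$cx == 50 & m$circles$r == 30))
  # linear center drift: cx = 100, 110, 120 at z = 1, 51, 101
  m <- interpolate_roi(circle_roi(1, 100, 80, 30), circle_roi(51, 110, 80, 30),
                       circle_roi(101, 120, 80, 30), 101)
  expect_equal(m$circles$cx[26], 105)
  # kink: cx = 100, 120, 120 -> segmentwise interpolation
  m <- interpolate_roi(circle_roi(1, 100, 80, 30), circle_roi(51, 120, 80, 30),
                       circle_roi(101, 120, 80, 30), 101)
  expect_equal(m$circles$cx[76], 120)
  expect_equal(m$circles$cx[26], 110)
  expect_error(interpolate_roi(circle_roi(5, 100, 80, 30),
                               circle_roi(51, 100, 80, 30),
                               circle_roi(101, 100, 80, 30), 101),
               "anchors")
  expect_error(circle_roi(1, 10, 10, -2), "r")
  # circle exceeding the slice bounds is rejected when shape is known
  expect_error(interpolate_roi(circle_roi(1, 10, 50, 30),
                               circle_roi(51, 10, 50, 30),
                               circle_roi(101, 10, 50, 30), 101,
                               slice_shape = c(100, 100)),
               "bounds")
})

test_that("apply_mask zeroes outside the circle, matching disk-area counts", {
  vol <- gray_volume(array(100, c(41, 41, 5)))
  m <- interpolate_roi(circle_roi(1, 21, 21, 10), circle_roi(3, 21, 21, 10),
                       circle_roi(5, 21, 21, 10), 5)
  out <- apply_mask(vol, m)
  # pixel-in-circle counting oracle
  disk <- sum(outer((1:41 - 21)^2, (1:41 - 21)^2, "+") <= 100)
  expect_equal(sum(out$data[, , 3] > 0), disk)
  # full-slice circle is the identity
  big <- interpolate_roi(circle_roi(1, 21, 21, 29), circle_roi(3, 21, 21, 29),
                         circle_roi(5, 21, 21, 29), 5)
  expect_true(all(apply_mask(vol, big)$data == 100))
  # extended mask is a superset of the bounded mask
  outb <- apply_mask(vol, m, extended = FALSE)
  oute <- apply_mask(vol, m, extended = TRUE)
  expect_true(all(oute$data[outb$data > 0] > 0))
  expect_gt(sum(oute$data > 0), sum(outb$data > 0))
  expect_error(apply_mask(gray_volume(array(0, c(41, 41, 4))), m), "depth")
})

test_that("find_peaks locates the wall and matrix maxima", {
  # two-delta histogram {60: lots, 200: more}
  vol <- gray_volume(array(c(rep(60, 4000), rep(200, 8000), rep(60, 1684)),
                           c(21, 26, 21)))
  m <- interpolate_roi(circle_roi(1, 11, 13, 8), circle_roi(11, 11, 13, 8),
                       circle_roi(21, 11, 13, 8), 21, extension = 50)
  p <- find_peaks(vol, m)
  expect_equal(p$P1, 60)
  expect_equal(p$P2, 200)
  # all mass below 128: no matrix peak
  low <- gray_volume(array(40, c(21, 26, 21)))
  expect_error(find_peaks(low, m), "matrix peak")
  hi <- gray_volume(array(200, c(21, 26, 21)))
  expect_error(find_peaks(hi, m), "wall peak")
})

test_that("find_peaks recovers phantom wall and matrix peaks across seeds", {
  # property over noise seeds: wall/matrix recovered within +-2 GV
  for (seed in 1:20) {
    ph <- generate_phantom(small_phantom_spec(seed = seed, noise_sd = 4))
    p <- find_peaks(nlm_denoise(ph$volume, t_con = 20), ph$roi)
    expect_lte(abs(p$P1 - 60), 2)
    expect_lte(abs(p$P2 - 150), 2)
  }
})
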