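# Phantom generator: determinism, ground-truth bookkeeping, histogram
# composition, and the truth-matching metrics.

test_that("the phantom is deterministic and honors its spec", {
  spec <- small_phantom_spec(seed = 5)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$mask$data, b$truth$mask$data)
  # different seed, different phantom
  c2 <- generate_phantom(small_phantom_spec(seed = 6))
  expect_false(identical(a$volume$data, c2$volume$data))
  # generating a phantom does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_phantom(small_phantom_spec(seed = 7)))
  after <- rnorm(1)
  expect_identical(before, after)
  expect_error(phantom_spec(root_diameters = c(1, 8)), "diameters")
})

test_that("zero roots give empty truth; a vertical tube gives exact length", {
  ph0 <- generate_phantom(small_phantom_spec(seed = 2,
                                             root_diameters = numeric(0)))
  expect_false(any(ph0$truth$mask$data))
  expect_equal(ph0$truth$total_length_um, 0)
  # truth length equals the polyline arithmetic
  ph <- generate_phantom(small_phantom_spec(seed = 3))
  seg_len <- sum(vapply(ph$truth$centerlines, function(p)
    sum(sqrt(diff(p$x)^2 + diff(p$y)^2 + diff(p$z)^2)), numeric(1)))
  expect_equal(ph$truth$total_length_um, seg_len * 45)
  expect_equal(sum(ph$truth$length_per_class_um), ph$truth$total_length_um,
               tolerance = 1e-9)
  # centerline table covers every polyline
  tab <- truth_centerline_table(ph$truth)
  expect_equal(length(unique(tab$root)), length(ph$truth$centerlines))
})

test_that("the phantom histogram shows the wall and matrix peaks", {
  ph <- generate_phantom(small_phantom_spec(seed = 9))
  p <- find_peaks(ph$volume, ph$roi)
  expect_lte(abs(p$P1 - 60), 2)
  expect_lte(abs(p$P2 - 150), 2)
  # gray-value ordering: pore < root < matrix < (wall below 128)
  expect_lt(p$P1, 128)
  expect_gte(p$P2, 128)
})

test_that("truth matching scores behave as designed", {
  ph <- generate_phantom(small_phantom_spec(seed = 4))
  # rasterized truth matches itself almost perfectly
  self <- evaluate_against_truth(ph$truth$mask, ph$truth)
  expect_gte(self$length_recall, 0.9)
  expect_gte(self$length_precision, 0.95)
  # empty segmentation: zero recall
  empty <- binary_volume(array(FALSE, dim(ph$truth$mask$data)))
  expect_equal(evaluate_against_truth(empty, ph$truth)$length_recall, 0)
  # a spurious elongated object lowers precision but not recall
  spur <- ph$truth$mask
  spur$data[10:12, 10:12, 20:70] <- TRUE
  with_spur <- evaluate_against_truth(spur, ph$truth)
  expect_lt(with_spur$length_precision, self$length_precision)
  expect_gte(with_spur$length_recall, self$length_recall - 0.02)
  expect_error(evaluate_against_truth(
    binary_volume(array(FALSE, c(4, 4, 4))), ph$truth), "mismatch")
})
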