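# Volume container, file formats, and resolution plumbing.

test_that("TIFF and NRRD round trips are bit-exact", {
  set.seed(4)
  vol <- gray_volume(array(sample(0:255, 10 * 7 * 5, TRUE), c(10, 7, 5)))
  vol16 <- gray_volume(array(sample(0:65535, 6 * 6 * 4, TRUE), c(6, 6, 4)),
                       bit_depth = 16L)
  for (ext in c("tif", "nrrd")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_volume(vol, f)
    back <- read_volume(f)
    expect_volumes_equal(vol, back)
    expect_equal(back$bit_depth, 8L)
    f2 <- tempfile(fileext = paste0(".", ext))
    write_volume(vol16, f2)
    back16 <- read_volume(f2)
    expect_volumes_equal(vol16, back16)
    expect_equal(back16$bit_depth, 16L)
  }
  # NRRD carries the voxel size; TIFF takes it from the caller
  f <- tempfile(fileext = ".nrrd")
  write_volume(gray_volume(array(0, c(3, 3, 3)), voxel_size_um = 20), f)
  expect_equal(read_volume(f)$voxel_size_um, 20)
})

test_that("binary volumes are written as 8-bit 0/255", {
  m <- array(FALSE, c(4, 4, 4))
  m[2, 3, 1] <- TRUE
  f <- tempfile(fileext = ".tif")
  write_volume(binary_volume(m), f)
  back <- read_volume(f)
  expect_equal(sum(back$data == 255), 1L)
  expect_equal(sum(back$data == 0), 63L)
  expect_equal(back$data[2, 3, 1], 255)
})

test_that("reader rejects what it cannot represent", {
  # single-page TIFF is not a 3D volume
  f <- tempfile(fileext = ".tif")
  rootct:::write_tiff_stack(array(0, c(4, 4, 1)), f)
  expect_error(read_volume(f), "not a 3D")
  expect_error(read_volume(tempfile(fileext = ".tif")), "not found")
  expect_error(read_volume(tempfile(fileext = ".xyz")), "format")
  # garbage file
  f2 <- tempfile(fileext = ".nrrd")
  writeLines("not a header", f2)
  expect_error(read_volume(f2), "NRRD")
  expect_error(gray_volume(matrix(0, 3, 3)), "3D")
  expect_error(gray_volume(array(300, c(2, 2, 2)), bit_depth = 8L), "outside")
  expect_error(gray_volume(array(0, c(2, 2, 2)), bit_depth = 12), "bit depth")
})

test_that("downscale is block-mean pooling", {
  # constant volume stays constant at half size
  vol <- gray_volume(array(7, c(8, 8, 8)))
  down <- downscale(vol, 2)
  expect_equal(dim(down$data), c(4L, 4L, 4L))
  expect_true(all(down$data == 7))
  expect_equal(down$voxel_size_um, 90)
  # factor 1 is the identity
  expect_volumes_equal(downscale(vol, 1), vol)
  # known 2x2x2 blocks vs a brute-force block-averaging oracle
  set.seed(12)
  v <- random_volume(6)
  down <- downscale(v, 2)
  oracle <- array(0, c(3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3)
    oracle[i, j, k] <- mean(v$data[(2 * i - 1):(2 * i),
                                   (2 * j - 1):(2 * j),
                                   (2 * k - 1):(2 * k)])
  expect_equal(down$data, oracle)
  # truncated edges are dropped; retained-block mean is preserved
  v7 <- random_volume(7)
  down <- downscale(v7, 2)
  expect_equal(dim(down$data), c(3L, 3L, 3L))
  expect_equal(mean(down$data), mean(v7$data[1:6, 1:6, 1:6]))
  expect_error(downscale(v7, 10), "dimension")
})

test_that("upscale_mask replicates and pads", {
  m <- array(FALSE, c(3, 3, 3))
  m[2, 2, 2] <- TRUE
  up <- upscale_mask(binary_volume(m), c(6, 6, 6))
  expect_equal(sum(up$data), 8L)
  expect_true(all(up$data[3:4, 3:4, 3:4]))
  # empty stays empty; odd target shapes pad with background
  up0 <- upscale_mask(binary_volume(array(FALSE, c(3, 3, 3))), c(7, 7, 7))
  expect_equal(dim(up0$data), c(7L, 7L, 7L))
  expect_false(any(up0$data))
  expect_error(upscale_mask(binary_volume(m), c(10, 6, 6)), "incompatible")
})

test_that("downscale then upscale of a solid cube agrees within a 1-voxel shell", {
  m <- array(FALSE, c(12, 12, 12))
  m[3:10, 3:10, 3:10] <- TRUE
  vol <- gray_volume(array(255 * m, dim(m)))
  down <- downscale(vol, 2)
  up <- upscale_mask(binary_volume(down$data >= 128), c(12, 12, 12))
  # set difference restricted to a 1-voxel shell of the original surface
  diff <- xor(up$data, m)
  if (any(diff)) {
    co <- which(diff, arr.ind = TRUE)
    # distance to the cube surface is at most 1
    inside_dist <- pmin(abs(co - 2.5), abs(co - 10.5))
    expect_true(all(apply(inside_dist, 1, min) <= 1))
  }
  succeed()
})
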