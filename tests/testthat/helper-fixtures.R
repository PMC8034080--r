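# Fixture builders shared across the test files. Everything is generated
# in code; no binary fixtures on disk.

# small gray volume with values filled from a function of (x, y, z)
make_volume <- function(nx, ny, nz, fill = function(x, y, z) 0,
                        voxel_size_um = 45, bit_depth = 8L) {
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny), z = seq_len(nz))
  gray_volume(array(fill(g$x, g$y, g$z), c(nx, ny, nz)),
              voxel_size_um = voxel_size_um, bit_depth = bit_depth)
}

# axis-aligned solid cylinder mask along z with integer-centered axis
make_cylinder_mask <- function(d, len, margin = 6) {
  n <- d + 2 * margin + 1 - ((d + 2 * margin + 1) %% 2 == 0) # odd
  cyl <- render_cylinder(d, shape = c(n, n, len))
  binary_volume(cyl$data >= 128, voxel_size_um = 45)
}

# small pot phantom spec scaled down for fast tests
small_phantom_spec <- function(..., root_diameters = c(4, 8), seed = 1L) {
  phantom_spec(shape = 96, wall_thickness = 12, roi_radius = 30,
               root_diameters = root_diameters, seed = seed, ...)
}

# deterministic random 8-bit volume
random_volume <- function(n = 32, seed = 99) {
  set.seed(seed)
  gray_volume(array(sample(0:255, n^3, replace = TRUE), c(n, n, n)))
}

expect_volumes_equal <- function(a, b) {
  expect_equal(dim(a$data), dim(b$data))
  expect_true(all(a$data == b$data))
}
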