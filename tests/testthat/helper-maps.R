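# Small symmetric test lattices built in code.

# RAS affine with isotropic voxels, grid centred on world (0,0,0)
centered_affine <- function(dm, voxel = 2) {
  aff <- diag(c(voxel, voxel, voxel, 1))
  aff[1:3, 4] <- -voxel * (dm - 1) / 2
  aff
}

# stat_map from values (vector or array) on a centred symmetric grid
make_map <- function(values, dm = NULL, voxel = 2, id = "t") {
  if (is.null(dm)) dm <- dim(as.array(values))
  stat_map(array(values, dim = dm), centered_affine(dm, voxel), id = id)
}

# map with noise plus a hot blob on one side; dominant left if side = "left"
lateralised_map <- function(dm = c(6, 6, 6), side = "left", amp = 10,
                            noise_sd = 1, seed = 1, voxel = 2, id = side) {
  set.seed(seed)
  v <- array(rnorm(prod(dm), sd = noise_sd), dim = dm)
  ix <- if (side == "left") 2L else dm[1] - 1L
  v[ix, ceiling(dm[2] / 2), ceiling(dm[3] / 2)] <-
    v[ix, ceiling(dm[2] / 2), ceiling(dm[3] / 2)] + amp
  make_map(v, dm, voxel = voxel, id = id)
}

# small fast cohort spec for classifier tests
tiny_spec <- function(...) {
  cohort_spec(n_per_class = c(left = 14, bilateral = 6, right = 6,
                              inconclusive = 8),
              grid_shape = c(16L, 20L, 16L), voxel_mm = 8, ...)
}

# world x-coordinates of a centred axis, matching centered_affine
axis_world_test <- function(n, voxel = 2) voxel * (0:(n - 1)) - voxel * (n - 1) / 2

expect_same_values <- function(a, b, tol = 1e-12) {
  expect_equal(as.vector(a), as.vector(b), tolerance = tol)
}
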