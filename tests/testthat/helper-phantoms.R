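# Small fixtures built in code.

# axis-aligned cuboid mask on an isotropic grid
cuboid_mask <- function(shape, from, to, spacing = 0.1) {
  g <- array(FALSE, shape)
  g[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  mask_volume(g, rep(spacing, 3))
}

# a cube "standard" plus a reference equal to the cube with a small lobe
# translated `shift` voxels away along the first axis (gap >= 1 voxel)
lobe_pair <- function(shift, shape = c(40, 20, 20), spacing = 0.1) {
  std <- cuboid_mask(shape, c(5, 5, 5), c(14, 14, 14), spacing)
  ref <- std
  x0 <- 15 + shift
  ref$grid[x0:(x0 + 2), 8:10, 8:10] <- TRUE
  list(std = std, ref = ref)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
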