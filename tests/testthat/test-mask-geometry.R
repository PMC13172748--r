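test_that("mask_volume validates its invariants", {
  g <- array(FALSE, c(3, 3, 3))
  expect_error(mask_volume(array(FALSE, c(3, 3)), c(0.1, 0.1, 0.1)), "3-D")
  expect_error(mask_volume(g, c(0.1, -0.1, 0.1)), "positive")
  expect_error(mask_volume(g, c(0.1, 0.1)), "positive")
  g[1, 1, 1] <- TRUE
  m <- mask_volume(g, c(0.1, 0.2, 0.3))
  expect_equal(mask_volume_cc(m), 0.1 * 0.2 * 0.3)
  # numeric grids are binarised
  m2 <- mask_volume(array(c(0, 2, 0.5, rep(0, 24)), c(3, 3, 3)),
                    c(0.1, 0.1, 0.1))
  expect_equal(sum(m2$grid), 2L)
})

test_that("overlap_volumes handles identity, disjoint, and nested spheres", {
  m <- cuboid_mask(c(12, 12, 12), c(1, 1, 1), c(10, 10, 10))  # 1000 voxels
  ov <- overlap_volumes(m, m)
  expect_equal(ov$V_Std, 1.0)
  expect_equal(ov$V_I, 1.0)
  expect_equal(ov$V_Std_minus_I, 0)
  expect_equal(ov$V_Ref_minus_I, 0)

  a <- cuboid_mask(c(20, 10, 10), c(1, 1, 1), c(5, 5, 5))
  b <- cuboid_mask(c(20, 10, 10), c(12, 1, 1), c(16, 5, 5))
  ov <- overlap_volumes(a, b)
  expect_equal(ov$V_I, 0)
  expect_equal(ov$V_Std_minus_I, ov$V_Std)

  ph <- make_sphere_pair_uniform(r0 = 2.0, margin = 0.6, spacing = 0.1)
  ov <- overlap_volumes(ph$std, ph$ref)
  expect_rel_equal(ov$V_I, 4 * pi / 3 * 2^3, 0.01)  # nested: V_I = V_Std
  expect_equal(ov$V_Std_minus_I, 0)
})

test_that("overlap_volumes rejects mismatched grids and empty masks", {
  a <- cuboid_mask(c(10, 10, 10), c(2, 2, 2), c(4, 4, 4))
  b <- cuboid_mask(c(11, 10, 10), c(2, 2, 2), c(4, 4, 4))
  expect_error(overlap_volumes(a, b), "shape")
  c1 <- cuboid_mask(c(10, 10, 10), c(2, 2, 2), c(4, 4, 4), spacing = 0.2)
  expect_error(overlap_volumes(a, c1), "spacing")
  d <- a; d$origin <- c(1, 0, 0)
  expect_error(overlap_volumes(a, d), "origin")
  empty <- mask_volume(array(FALSE, c(10, 10, 10)), rep(0.1, 3))
  expect_error(overlap_volumes(empty, a), "degenerate")
})

test_that("distance_field gives physical center-to-center distances", {
  g <- array(FALSE, c(7, 7, 7)); g[4, 4, 4] <- TRUE
  m <- mask_volume(g, c(0.1, 0.1, 0.1))
  d <- distance_field(m)
  expect_equal(d[4, 4, 4], 0)
  expect_equal(d[5, 4, 4], 0.1)
  expect_equal(d[5, 5, 4], 0.1 * sqrt(2))
  expect_equal(d[5, 5, 5], 0.1 * sqrt(3))
  expect_equal(d[7, 4, 4], 0.3)
  expect_true(all(is.finite(d)) && all(d >= 0))

  # anisotropic spacing
  ma <- mask_volume(g, c(0.1, 0.2, 0.3))
  da <- distance_field(ma)
  expect_equal(da[5, 4, 4], 0.1)
  expect_equal(da[4, 5, 4], 0.2)
  expect_equal(da[4, 4, 5], 0.3)
  expect_equal(da[5, 5, 5], sqrt(0.01 + 0.04 + 0.09))

  full <- mask_volume(array(TRUE, c(4, 4, 4)), rep(0.1, 3))
  expect_true(all(distance_field(full) == 0))
  empty <- mask_volume(array(FALSE, c(4, 4, 4)), rep(0.1, 3))
  expect_error(distance_field(empty), "degenerate")
})

test_that("distance field of a digital sphere approximates radial distance", {
  sph <- sphere_mask(2.0, spacing = 0.1, pad = 1.0)
  d <- distance_field(sph)
  ctr <- (dim(sph$grid) - 1) / 2 * sph$spacing
  ax <- lapply(1:3, function(a) (seq_len(dim(sph$grid)[a]) - 1) * 0.1 - ctr[a])
  rho <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`))
  out <- rho > 2.0
  diag_len <- 0.1 * sqrt(3)
  expect_true(all(abs(d[out] - (rho[out] - 2.0)) <= diag_len))
})

test_that("expand is the identity at 0, monotone, and matches enumeration", {
  g <- array(FALSE, c(9, 9, 9)); g[5, 5, 5] <- TRUE
  m <- mask_volume(g, rep(0.1, 3))
  expect_identical(expand(m, 0)$grid, m$grid)
  # one isotropic spacing: 6-connected neighborhood only (diagonals at
  # 0.1*sqrt(2) are excluded)
  e1 <- expand(m, 0.1)
  expect_equal(sum(e1$grid), 7L)
  expect_true(all(e1$grid[cbind(c(4, 6, 5, 5, 5, 5, 5),
                                c(5, 5, 4, 6, 5, 5, 5),
                                c(5, 5, 5, 5, 4, 6, 5))]))
  # monotone nesting
  e2 <- expand(m, 0.2)
  expect_true(all(e1$grid <= e2$grid))
  expect_error(expand(m, -0.1), "non-negative")
})

test_that("expanding a digital sphere reproduces the enlarged sphere volume", {
  # distances run center-to-center, so the expansion undershoots the
  # analytic 2.6 cm sphere by a fraction of a voxel at its surface
  sph <- sphere_mask(2.0, spacing = 0.1, pad = 1.0)
  e <- expand(sph, 0.6)
  expect_rel_equal(mask_volume_cc(e), 4 * pi / 3 * 2.6^3, 0.03)
})

test_that("band_nonoverlap uses the average-unit-distance rule", {
  # representative distances: the mean of the 0.1 cm unit distances a band
  # spans; (0.1+0.2+0.3)/3 = 0.2 for the first 0.3 cm band
  ph <- make_sphere_pair_uniform(r0 = 2.0, margin = 0.6, spacing = 0.1)
  shell <- mask_volume(ph$ref$grid & !ph$std$grid, ph$ref$spacing)
  dec <- band_nonoverlap(shell, ph$std, w = 0.3)
  expect_equal(dec$bands$distance_cm[1:2], c(0.2, 0.5))
  dec6 <- band_nonoverlap(shell, ph$std, w = 0.6)
  expect_equal(dec6$bands$distance_cm[1], (0 + 0.1 + 0.6) / 2)
})

test_that("empty regions give empty decompositions", {
  ph <- make_sphere_pair_uniform(r0 = 1.0, margin = 0.3, spacing = 0.1)
  none <- mask_volume(array(FALSE, dim(ph$std$grid)), ph$std$spacing)
  dec <- band_nonoverlap(none, ph$std, w = 0.3)
  expect_equal(nrow(dec$bands), 0L)
  expect_equal(dec$total_volume_cc, 0)
  expect_equal(equivalent_volume(dec, ev_params()), 0)
})

test_that("band volumes partition the region and nest like expansions", {
  ph <- make_sphere_pair_uniform(r0 = 1.5, margin = 0.5, spacing = 0.1)
  shell <- mask_volume(ph$ref$grid & !ph$std$grid, ph$ref$spacing)
  dec <- band_nonoverlap(shell, ph$std, w = 0.3)
  # conservation is exact: voxel counts partition
  expect_equal(sum(dec$bands$volume_cc), mask_volume_cc(shell))
  expect_true(all(diff(dec$bands$band) > 0))
  expect_true(all(diff(dec$bands$distance_cm) > 0))
  expect_true(all(dec$bands$volume_cc >= 0))
  # band k equals expand(other, k*w) \ expand(other, (k-1)*w) within region
  for (k in dec$bands$band) {
    ring <- expand(ph$std, k * 0.3)$grid & !expand(ph$std, (k - 1) * 0.3)$grid
    vol_k <- sum(ring & shell$grid) * prod(shell$spacing)
    expect_equal(dec$bands$volume_cc[dec$bands$band == k], vol_k)
  }
})

test_that("continuous and banded modes agree when voxels are re-binned", {
  ph <- make_sphere_pair_displaced(1.5, 2.0, offset = 0.4, spacing = 0.1)
  region <- mask_volume(ph$ref$grid & !ph$std$grid, ph$ref$spacing)
  b <- band_nonoverlap(region, ph$std, w = 0.3)
  cont <- band_nonoverlap(region, ph$std, w = 0.3, mode = "continuous")
  k <- pmax(1, ceiling((cont$bands$distance_cm - 1e-8) / 0.3))
  rebinned <- tapply(cont$bands$volume_cc, k, sum)
  expect_equal(as.numeric(rebinned[as.character(b$bands$band)]),
               b$bands$volume_cc)
  expect_equal(cont$total_volume_cc, b$total_volume_cc)
})

test_that("band_nonoverlap enforces its preconditions", {
  ph <- make_sphere_pair_uniform(r0 = 1.0, margin = 0.3, spacing = 0.1)
  shell <- mask_volume(ph$ref$grid & !ph$std$grid, ph$ref$spacing)
  expect_error(band_nonoverlap(ph$ref, ph$std, w = 0.3), "disjoint")
  expect_error(band_nonoverlap(shell, ph$std, w = -0.3), "positive")
  expect_error(band_nonoverlap(shell, ph$std, w = 0.25), "multiple")
  expect_error(band_nonoverlap(shell, ph$std, w = 0.3, max_bands = 1L),
               "bands")
})
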