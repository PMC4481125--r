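test_that("rigid transforms compose, invert and serialise exactly", {
  tf <- rigid_transform(c(4, -7, 12), c(3.5, -2, 8), center = c(10, 20, 5))
  inv <- invert_transform(tf)
  set.seed(8)
  pts <- matrix(rnorm(30, sd = 20), ncol = 3)
  back <- transform_points(inv, transform_points(tf, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
  comp <- compose_transforms(inv, tf)
  expect_lt(max(abs(comp$rotation)), 1e-9)
  expect_lt(max(abs(comp$translation)), 1e-9)
  # rigid transforms preserve distances
  d0 <- dist(pts)
  d1 <- dist(transform_points(tf, pts))
  expect_lt(max(abs(d0 - d1)), 1e-9)

  f <- withr::local_tempfile(fileext = ".txt")
  write_transform(tf, f)
  tf2 <- read_transform(f)
  expect_equal(tf2$rotation, tf$rotation, tolerance = 1e-10)
  expect_equal(tf2$translation, tf$translation, tolerance = 1e-10)
  expect_equal(tf2$center, tf$center, tolerance = 1e-10)
})

test_that("mask resampling preserves lattice structure", {
  d <- c(24, 24, 24)
  g <- volume_grid(d)
  cx <- (d - 1) / 2
  idx <- expand.grid(x = 1:d[1], y = 1:d[2], z = 1:d[3])
  r2 <- (idx$x - 1 - cx[1])^2 + (idx$y - 1 - cx[2])^2 +
    (idx$z - 1 - cx[3])^2
  sphere <- binary_mask(array(r2 <= 8^2, d), g)

  # identity transform, same grid: bit-identical mask
  id <- rigid_transform(center = grid_phys_center(g))
  expect_identical(resample_mask(sphere, id, g)$values, sphere$values)

  # integer-voxel translation: voxel count conserved exactly
  sh <- rigid_transform(translation = c(3, -2, 1),
                        center = grid_phys_center(g))
  shifted <- resample_mask(sphere, sh, g)
  expect_identical(sum(shifted$values), sum(sphere$values))

  # 5 degree rotation: volume conserved within the voxelisation bound
  rot <- rigid_transform(rotation = c(0, 0, 5),
                         center = grid_phys_center(g))
  rotated <- resample_mask(sphere, rot, g)
  expect_lt(abs(sum(rotated$values) - sum(sphere$values)) /
              sum(sphere$values), 0.03)
})

test_that("registering a volume to itself returns the identity", {
  ph <- generate_phantom(identity_small_spec())
  tf <- rigid_register(ph$t1, ph$t1,
                       registration_params(search_range = 0))
  expect_lt(max(abs(tf$translation)), 0.1)
  expect_lt(max(abs(tf$rotation)), 0.1)
})

test_that("known rigid offsets are recovered on the phantom", {
  # translation-only case
  sp <- small_phantom_spec(
    inter_scan_transform = rigid_transform(
      translation = c(5, 0, 0),
      center = grid_phys_center(volume_grid(c(48, 48, 32)))))
  ph <- generate_phantom(sp)
  tf <- rigid_register(ph$study$pre, ph$t1)
  expect_lt(max(abs(tf$translation - c(5, 0, 0))), 0.5)
  expect_lt(max(abs(tf$rotation)), 1)

  # rotation about z through the volume centre
  sp2 <- small_phantom_spec(
    inter_scan_transform = rigid_transform(
      rotation = c(0, 0, 5),
      center = grid_phys_center(volume_grid(c(48, 48, 32)))))
  ph2 <- generate_phantom(sp2)
  tf2 <- rigid_register(ph2$study$pre, ph2$t1)
  expect_lt(max(abs(tf2$rotation - c(0, 0, 5))), 1)
  expect_lt(max(abs(tf2$translation)), 0.5)

  # mask nesting survives the transfer
  br <- segment_breast(ph$t1)
  fg <- segment_fgt(ph$t1, br)
  br_dce <- resample_mask(br, tf, ph$study$pre$grid)
  fg_dce <- resample_mask(fg, tf, ph$study$pre$grid)
  expect_false(any(fg_dce$values & !br_dce$values))
})

test_that("registration rejects constant volumes", {
  expect_error(rigid_register(const_vol(1, c(8, 8, 8)),
                              const_vol(2, c(8, 8, 8))),
               "constant")
})
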