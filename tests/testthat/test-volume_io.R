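test_that("NIfTI round-trip preserves values, spacing and origin", {
  set.seed(3)
  g <- volume_grid(c(5, 6, 7), spacing = c(0.7, 0.7, 3.0),
                   origin = c(5, -2, 1))
  v <- volume_image(array(rnorm(prod(g$dims)), g$dims), g)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  r <- read_volume(f)
  expect_equal(r$values, v$values, tolerance = 1e-12)
  # header pixdim/qoffset are float32: passthrough to that precision
  expect_equal(r$grid$spacing, c(0.7, 0.7, 3.0), tolerance = 1e-6)
  expect_equal(r$grid$origin, c(5, -2, 1), tolerance = 1e-6)

  ones <- const_vol(1)
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(ones, f2)
  r2 <- read_volume(f2)
  expect_identical(r2$values, ones$values)
  expect_identical(r2$grid$spacing, c(1, 1, 1))
})

test_that("read_volume rejects missing and 4D inputs", {
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "not found")

  f4 <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(1, c(4, 4, 4, 2))), f4)
  expect_error(read_volume(f4), "3D")
  # a zero spacing component is rejected at the grid level (the NIfTI
  # library sanitises zero pixdims before they reach the reader)
  expect_error(volume_grid(c(4, 4, 4), c(0.7, 0, 3)), "spacing")
})

test_that("volume_grid and mask volumes enforce their invariants", {
  expect_error(volume_grid(c(4, 4), c(1, 1, 1)), "dims")
  expect_error(volume_grid(c(4, 4, 4), c(1, 0, 1)), "spacing")
  expect_error(volume_image(array(c(1, NA), c(1, 1, 2))), "finite")

  g <- volume_grid(c(10, 10, 10))
  m <- binary_mask(array(TRUE, c(10, 10, 10)), g)
  expect_equal(mask_volume_cc(m), 1)
  g2 <- volume_grid(c(1, 1, 1), spacing = c(0.7, 0.7, 3.0))
  m2 <- binary_mask(array(TRUE, c(1, 1, 1)), g2)
  expect_equal(mask_volume_cc(m2), 0.00147)
  expect_equal(mask_volume_cc(binary_mask(array(FALSE, c(10, 10, 10)), g)),
               0)
})

test_that("subtraction images follow post minus pre, unclamped", {
  pre <- const_vol(100)
  study <- dce_study(pre, list(const_vol(130), const_vol(90)))
  expect_true(all(derive_subtraction(study, 1)$values == 30))
  expect_true(all(derive_subtraction(study, 2)$values == -10))
  expect_error(derive_subtraction(study, 3), "out of range")

  # derived SUB + pre reconstructs post exactly
  set.seed(4)
  g <- volume_grid(c(4, 4, 4))
  pre2 <- volume_image(array(runif(64, 50, 150), g$dims), g)
  post2 <- volume_image(array(runif(64, 50, 250), g$dims), g)
  st2 <- dce_study(pre2, list(post2))
  expect_identical(derive_subtraction(st2, 1)$values + pre2$values,
                   post2$values)
})

test_that("stored SUB volumes are returned bit-identically", {
  pre <- const_vol(100)
  sub_stored <- const_vol(42.5)
  study <- dce_study(pre, list(const_vol(130)), subs = list(sub_stored))
  expect_identical(derive_subtraction(study, 1), sub_stored)
})

test_that("dce_study rejects mismatched grids", {
  pre <- const_vol(1)
  bad <- const_vol(1, spacing = c(2, 1, 1))
  expect_error(dce_study(pre, list(bad)), "grid")
  expect_error(dce_study(pre, list(const_vol(1)), subs = list(bad)),
               "grid")
  expect_error(dce_study(pre, list(const_vol(1)),
                         subs = list(const_vol(1), const_vol(1))),
               "one volume per")
})
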