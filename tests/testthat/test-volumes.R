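test_that("grid construction validates shape, spacing and origin", {
  g <- volume_grid(c(10, 10, 10), 2)
  expect_equal(voxel_volume_mm3(g), 8)
  expect_equal(g$origin_mm, c(-9, -9, -9))  # centred by default
  expect_error(volume_grid(c(0, 5, 5), 2), "shape")
  expect_error(volume_grid(c(5, 5, 5), c(2, -1, 2)), "spacing")
  expect_error(volume_grid(c(5, 5), 2), "shape")
})

test_that("scalar volumes reject non-finite values and wrong shapes", {
  g <- tiny_grid()
  expect_error(scalar_volume(array(0, c(4, 5, 5)), g), "dimensions")
  bad <- array(1, c(5, 5, 5)); bad[3, 3, 3] <- NaN
  expect_error(scalar_volume(bad, g), "non-finite")
  expect_error(mask_volume(array(2, c(5, 5, 5)), g), "0 or 1")
})

test_that("volume_cc matches hand counts and is additive over disjoint masks", {
  g <- volume_grid(c(10, 10, 10), 2)
  m <- array(FALSE, c(10, 10, 10)); m[1:4, 1:5, 1:5] <- TRUE  # 100 voxels
  expect_equal(volume_cc(mask_volume(m, g)), 0.8)
  expect_equal(volume_cc(mask_volume(array(FALSE, c(10, 10, 10)), g)), 0)
  g1 <- volume_grid(c(10, 10, 10), 1)
  expect_equal(volume_cc(mask_volume(array(TRUE, c(10, 10, 10)), g1)), 1)
  a <- random_mask(g, 1, 0.2)$values
  b <- random_mask(g, 2, 0.2)$values & !a   # disjoint by construction
  expect_equal(volume_cc(mask_volume(a | b, g)),
               volume_cc(mask_volume(a, g)) + volume_cc(mask_volume(b, g)))
})

test_that("NIfTI round trip preserves values, spacing and origin", {
  dir <- withr::local_tempdir()
  g <- volume_grid(c(10, 10, 10), 2, origin_mm = c(-9, -9, -5))
  v <- random_scalar(g, 5)
  p <- file.path(dir, "v.nii.gz")
  write_volume(v, p)
  v2 <- read_volume(p)
  expect_equal(v2$grid$shape, g$shape)
  expect_equal(v2$grid$spacing_mm, g$spacing_mm, tolerance = 1e-6)
  expect_equal(v2$grid$origin_mm, g$origin_mm, tolerance = 1e-3)
  expect_equal(v2$values, v$values, tolerance = 1e-6)  # float32 storage
  m <- random_mask(g, 6)
  pm <- file.path(dir, "m.nii")
  write_volume(m, pm)
  back <- read_volume(pm)            # read as scalar: on-disk values 0/1
  expect_true(all(back$values %in% c(0, 1)))
  m2 <- read_volume(pm, as_mask = TRUE)
  expect_identical(m2$values, m$values)
})

test_that("I/O errors are descriptive", {
  dir <- withr::local_tempdir()
  g <- tiny_grid()
  expect_error(read_volume(file.path(dir, "nope.nii")), "no such file")
  expect_error(write_volume(random_scalar(g, 1), file.path(dir, "sub", "x.nii")),
               "directory")
  # 4-D file rejected
  arr4 <- array(0, c(5, 5, 5, 2))
  p4 <- file.path(dir, "four.nii")
  RNifti::writeNifti(RNifti::asNifti(arr4), p4)
  expect_error(read_volume(p4), "3-D")
  # NaN voxel in file rejected
  arrn <- array(1, c(5, 5, 5)); arrn[1, 1, 1] <- NaN
  pn <- file.path(dir, "nan.nii")
  RNifti::writeNifti(RNifti::asNifti(arrn), pn)
  expect_error(read_volume(pn), "non-finite")
})

test_that("assert_same_grid accepts copies and names the first mismatch", {
  g <- tiny_grid()
  v <- random_scalar(g, 1)
  expect_silent(assert_same_grid(list(v, v)))
  g2 <- volume_grid(c(5, 5, 5), 2.5)
  expect_error(assert_same_grid(list(a = v, b = random_scalar(g2, 2))),
               "spacing")
  g3 <- volume_grid(c(5, 5, 6), 2)
  expect_error(assert_same_grid(list(v, scalar_volume(array(0, c(5, 5, 6)), g3))),
               "shape")
  expect_error(assert_same_grid(list()), "nonempty")
})

test_that("gaussian smoothing preserves constants, mass and linearity", {
  g <- volume_grid(c(21, 21, 21), 2)
  const <- scalar_volume(array(7, g$shape), g)
  expect_equal(gaussian_smooth(const, 12)$values, const$values, tolerance = 1e-10)
  imp <- array(0, g$shape); imp[11, 11, 11] <- 1
  sm <- gaussian_smooth(scalar_volume(imp, g), 12)
  expect_equal(sum(sm$values), 1, tolerance = 1e-6)       # mass conserved
  expect_lt(max(sm$values), 1)                            # averaging
  u <- random_scalar(g, 3); v <- random_scalar(g, 4)
  lin <- scalar_volume(2 * u$values - 3 * v$values, g)
  expect_equal(gaussian_smooth(lin, 8)$values,
               2 * gaussian_smooth(u, 8)$values - 3 * gaussian_smooth(v, 8)$values,
               tolerance = 1e-8)
  expect_error(gaussian_smooth(const, 0), "positive")
})

test_that("hemisphere masks partition the grid minus the midline band", {
  g <- volume_grid(c(11, 5, 5), 2)        # odd x: a genuine midline column
  left <- hemisphere_mask(g, "left"); right <- hemisphere_mask(g, "right")
  expect_false(any(left$values & right$values))
  mid <- !(left$values | right$values)
  expect_equal(sum(mid), 5 * 5)           # exactly the x = 0 column
  expect_equal(sum(left$values) + sum(right$values) + sum(mid), prod(g$shape))
  # grid entirely at positive x
  gp <- volume_grid(c(4, 4, 4), 2, origin_mm = c(10, 0, 0))
  expect_equal(sum(hemisphere_mask(gp, "left")$values), 0)
  expect_equal(sum(hemisphere_mask(gp, "right")$values), prod(gp$shape))
})

test_that("connected components respect the connectivity scheme", {
  g <- volume_grid(c(6, 6, 6), 2)
  arr <- array(FALSE, g$shape)
  arr[1:2, 1:2, 1] <- TRUE        # blob of 4
  arr[4, 4, 4] <- TRUE            # isolated voxel
  arr[5, 5, 5] <- TRUE            # diagonal neighbour of the above
  lab26 <- label_components(mask_volume(arr, g), 26)
  expect_equal(sort(lab26$sizes, decreasing = TRUE), c(4, 2))
  lab6 <- label_components(mask_volume(arr, g), 6)
  expect_equal(sort(lab6$sizes, decreasing = TRUE), c(4, 1, 1))
  expect_equal(label_components(array(FALSE, g$shape))$sizes, integer(0))
})
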