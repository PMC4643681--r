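test_that("the single-case t statistic follows its closed form", {
  expect_equal(crawford_howell_t(100, 100, 3, 17)$t, 0)
  r <- crawford_howell_t(100 + 3, 100, 3, 100)   # x one sd above the mean
  expect_equal(r$t, 1 / sqrt(1.01), tolerance = 1e-12)
  expect_equal(r$df, 99L)
  up <- crawford_howell_t(105, 100, 2, 10)$t
  dn <- crawford_howell_t(95, 100, 2, 10)$t
  expect_equal(up, -dn)                           # antisymmetry
  expect_error(crawford_howell_t(1, 0, 1, 1), ">= 2")
  expect_error(crawford_howell_t(1, 0, 0, 10), "sd")
})

test_that("control references hold voxel-wise sample statistics", {
  g <- tiny_grid()
  v <- random_scalar(g, 1)
  ref_same <- fit_control_reference(list(v, v, v))
  expect_equal(max(ref_same$sd), 0)
  expect_equal(ref_same$n, 3L)
  a <- scalar_volume(array(98, g$shape), g)
  b <- scalar_volume(array(102, g$shape), g)
  ref <- fit_control_reference(list(a, b))
  expect_equal(ref$mean[1, 1, 1], 100)
  expect_equal(ref$sd[1, 1, 1], sqrt(8))          # |delta|/sqrt(2) = 2.828...
  expect_error(fit_control_reference(list(v)), "at least 2")
})

test_that("the t map equals the scalar statistic applied voxel by voxel", {
  g <- tiny_grid()
  controls <- lapply(1:8, function(i) random_scalar(g, 100 + i))
  ref <- fit_control_reference(controls)
  patient <- random_scalar(g, 200)
  tm <- t_map(patient, ref)
  # brute-force per-voxel loop
  expected <- array(NA_real_, g$shape)
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expected[i, j, k] <- crawford_howell_t(patient$values[i, j, k],
                                           ref$mean[i, j, k],
                                           ref$sd[i, j, k], ref$n)$t
  expect_lt(max(abs(tm$values - expected)), 1e-10)
  expect_equal(attr(tm, "df"), 7L)
  # patient identical to the control mean: all-zero map
  zero <- t_map(scalar_volume(ref$mean, g), ref)
  expect_equal(max(abs(zero$values)), 0)
})

test_that("degenerate (zero-sd) voxels yield t = 0 and are counted", {
  g <- tiny_grid()
  controls <- lapply(1:6, function(i) {
    v <- random_scalar(g, 300 + i)
    v$values[2, 2, 2] <- 50                        # identical across controls
    v
  })
  ref <- fit_control_reference(controls)
  patient <- random_scalar(g, 400)
  tm <- t_map(patient, ref)
  expect_equal(tm$values[2, 2, 2], 0)
  expect_gte(attr(tm, "degenerate_voxels"), 1)
})

test_that("lesion binarization selects the stated tail and cleans small clusters", {
  g <- volume_grid(c(8, 8, 8), 2)
  tv <- array(0, g$shape)
  tv[2:4, 2:4, 2:4] <- -5        # hypointense block of 27
  tv[7, 7, 7] <- -5              # isolated voxel
  tv[1, 8, 1] <- 5               # hyperintense voxel
  tm <- scalar_volume(tv, g)
  expect_equal(sum(binarize_lesion(scalar_volume(array(0, g$shape), g), 3)$values), 0)
  hypo <- binarize_lesion(tm, 3)
  expect_equal(sum(hypo$values), 28)
  expect_equal(sum(binarize_lesion(tm, 3, "hyperintense")$values), 1)
  expect_equal(sum(binarize_lesion(tm, 3, "two_sided")$values), 29)
  cleaned <- binarize_lesion(tm, 3, min_cluster_voxels = 2)
  expect_equal(sum(cleaned$values), 27)            # isolated voxel removed
  expect_error(binarize_lesion(tm, -1), "positive")
})

test_that("raising the threshold never adds voxels to the mask", {
  g <- tiny_grid()
  controls <- lapply(1:10, function(i) random_scalar(g, 500 + i))
  ref <- fit_control_reference(controls)
  tm <- t_map(random_scalar(g, 600), ref)
  sizes <- sapply(c(0.5, 1, 2, 3), function(th) sum(binarize_lesion(tm, th)$values))
  expect_true(all(diff(sizes) <= 0))
})

test_that("delineation composes its stages deterministically", {
  g <- volume_grid(c(16, 16, 16), 2)
  controls <- lapply(1:10, function(j) make_control_volume(g, 700 + j, noise_sd = 1))
  ref <- fit_control_reference(controls)
  pv <- make_patient_volume(make_control_volume(g, 55, noise_sd = 1),
                            c(4, 0, 0), c(6, 6, 6), intensity_drop = 12)
  d1 <- delineate(pv$image, ref)
  d2 <- delineate(pv$image, ref)
  expect_identical(d1$mask$values, d2$mask$values)
  expect_equal(d1$lesion_volume_cc, volume_cc(d1$mask))
  expect_equal(d1$report$df, 9L)
  # pure-noise patient at a stiff threshold: essentially nothing detected
  null <- delineate(make_control_volume(g, 56, noise_sd = 1), ref, t_threshold = 8)
  expect_lt(null$lesion_volume_cc, 0.05)
})

test_that("dice coefficient behaves at its extremes", {
  g <- tiny_grid()
  m <- random_mask(g, 9)
  expect_equal(dice_coefficient(m, m), 1)
  empty <- mask_volume(array(FALSE, g$shape), g)
  expect_equal(dice_coefficient(m, empty), 0)
  expect_equal(dice_coefficient(empty, empty), 1)
})
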