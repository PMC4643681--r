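test_that("the canonical registry enumerates 16 tracts by category", {
  reg <- canonical_tracts()
  expect_equal(nrow(reg), 16)
  expect_equal(sum(reg$category == "association"), 10)
  expect_equal(sum(reg$category == "commissural"), 2)
  expect_equal(sum(reg$category == "projection"), 4)
  expect_false(anyDuplicated(reg$name) > 0)
})

test_that("tract thresholding is inclusive at the boundary", {
  g <- tiny_grid()
  vals <- array(0, g$shape)
  vals[1, 1, 1] <- 0.2; vals[2, 1, 1] <- 0.5; vals[3, 1, 1] <- 0.8
  m <- threshold_tract(scalar_volume(vals, g), 0.5)
  expect_equal(which(m$values), c(2L, 3L))
  low <- scalar_volume(array(0.4, g$shape), g)
  expect_equal(sum(threshold_tract(low, 0.5)$values), 0)
  expect_error(threshold_tract(low, 0), "threshold")
  expect_error(threshold_tract(low, 1), "threshold")
})

test_that("overlap volumes match brute-force voxel counting exactly", {
  g <- volume_grid(c(7, 6, 5), 2)
  for (s in 1:10) {
    a <- random_mask(g, 1000 + s, 0.4)
    b <- random_mask(g, 2000 + s, 0.4)
    brute <- 0
    for (i in 1:7) for (j in 1:6) for (k in 1:5)
      if (a$values[i, j, k] && b$values[i, j, k]) brute <- brute + 1
    expect_identical(overlap_cc(a, b), brute * 8 / 1000)
  }
})

test_that("overlap is bounded by both masks and idempotent", {
  g <- volume_grid(c(10, 10, 10), 2)
  for (s in 1:100) {
    a <- random_mask(g, 3000 + s, runif(1, 0.05, 0.5))
    b <- random_mask(g, 4000 + s, runif(1, 0.05, 0.5))
    expect_lte(overlap_cc(a, b), min(volume_cc(a), volume_cc(b)))
  }
  m <- random_mask(g, 77)
  expect_equal(overlap_cc(m, m), volume_cc(m))
  disj <- mask_volume(array(FALSE, g$shape), g)
  expect_equal(overlap_cc(m, disj), 0)
  # 100-voxel lesion fully inside a tract at 2 mm isotropic: 0.8 cc
  lesion <- array(FALSE, g$shape); lesion[1:4, 1:5, 1:5] <- TRUE
  tract <- array(TRUE, g$shape)
  expect_equal(overlap_cc(mask_volume(lesion, g), mask_volume(tract, g)), 0.8)
})

test_that("the disconnection table is fully populated and consistent", {
  co <- small_cohort()
  tab <- build_disconnection_table(co$true_lesions, co$atlas, co$behaviour)
  expect_s3_class(tab, "disconnection_table")
  tract_cols <- attr(tab, "tract_cols")
  expect_equal(length(tract_cols), nrow(co$atlas$entries))
  expect_false(any(is.na(tab[, tract_cols])))
  # overlaps never exceed the lesion volume
  for (cl in tract_cols) expect_true(all(tab[[cl]] <= tab$lesion_volume_cc + 1e-12))
  # column-by-column equality with direct calls
  cores <- lapply(co$atlas$maps, threshold_tract)
  i <- 3
  for (tn in names(cores))
    expect_equal(tab[[paste0("disc_", tn)]][i],
                 overlap_cc(co$true_lesions[[tab$patient_id[i]]], cores[[tn]]))
  # id mismatch is refused
  bad <- co$behaviour; bad$patient_id[1] <- "P999"
  expect_error(build_disconnection_table(co$true_lesions, co$atlas, bad),
               "do not match")
})

test_that("an empty lesion yields zero volume and zero overlaps", {
  co <- small_cohort()
  lesions <- co$true_lesions
  empty <- mask_volume(array(FALSE, co$grid$shape), co$grid)
  lesions[[1]] <- empty
  tab <- build_disconnection_table(lesions, co$atlas, co$behaviour)
  row <- tab[tab$patient_id == names(lesions)[1], ]
  expect_equal(row$lesion_volume_cc, 0)
  expect_true(all(row[, attr(tab, "tract_cols")] == 0))
})

test_that("percent disconnected counts patients with any overlap", {
  co <- small_cohort()
  tab <- build_disconnection_table(co$true_lesions, co$atlas, co$behaviour)
  pct <- percent_disconnected(tab)
  manual <- 100 * colMeans(co$truth > 0)
  expect_equal(unname(pct[colnames(co$truth)]), unname(manual))
  # invariant under patient reordering
  perm <- sample(nrow(tab))
  tab2 <- tab[perm, ]
  attr(tab2, "tract_cols") <- attr(tab, "tract_cols")
  class(tab2) <- class(tab)
  expect_equal(percent_disconnected(tab2), pct)
})

test_that("group lesion overlap counts patients per voxel", {
  g <- volume_grid(c(6, 6, 6), 2)
  masks <- lapply(1:8, function(s) random_mask(g, 5000 + s, 0.3))
  ov <- group_lesion_overlap(masks)
  expect_lte(max(ov$values), 8)
  expect_equal(ov$values[2, 2, 2],
               sum(sapply(masks, function(m) m$values[2, 2, 2])))
  one <- group_lesion_overlap(masks[1])
  expect_equal(one$values, array(as.numeric(masks[[1]]$values), g$shape))
})

test_that("percent-scale atlases are normalised with a warning", {
  g <- tiny_grid()
  m <- scalar_volume(array(60, g$shape), g)   # 0-100 scale
  expect_warning(
    at <- tract_atlas("t1", "left", "association", list(m)),
    "percent scale")
  expect_equal(max(at$maps[["t1"]]$values), 0.6)
})
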