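test_that("control volumes are positive and deterministic in the seed", {
  g <- volume_grid(c(12, 12, 12), 2)
  a <- make_control_volume(g, 42)
  b <- make_control_volume(g, 42)
  c <- make_control_volume(g, 43)
  expect_identical(a$values, b$values)
  expect_gt(sum(a$values != c$values), 0)
  expect_true(all(a$values > 0))
})

test_that("tract maps peak on the centerline and decay with distance", {
  g <- volume_grid(c(21, 21, 21), 2)
  # centerline passing exactly through voxel centres at z = 0, x = 0
  sp <- tract_spec("t", "left", cbind(c(0, 0), c(-10, 10), c(0, 0)),
                   radius_mm = 6, peak_probability = 0.9)
  m <- make_tract_map(sp, g)
  expect_equal(max(m$values), 0.9, tolerance = 1e-9)
  expect_equal(m$values[11, 11, 11], 0.9, tolerance = 1e-9)
  corner <- m$values[1, 1, 1]              # far corner: >> radius away
  expect_lt(corner, 1e-6)
  core <- threshold_tract(m, 0.5)
  expect_gt(sum(core$values), 0)
  expect_true(all(m$values[core$values] >= 0.5))
  # centerline outside the grid is rejected
  bad <- tract_spec("b", "left", cbind(c(0, 0), c(-99, 99), c(0, 0)), 6)
  expect_error(make_tract_map(bad, g), "bounding box")
})

test_that("ellipsoid masks approximate the analytic volume", {
  g <- volume_grid(c(40, 40, 40), 1)
  radii <- c(6, 8, 5)
  m <- ellipsoid_mask(g, c(0, 0, 0), radii)
  analytic <- 4 / 3 * pi * prod(radii)
  # voxelization error bounded by one voxel layer over the surface
  surface <- 4 * pi * (prod(radii)^(2 / 3))
  expect_lt(abs(sum(m$values) - analytic), surface * 1.2)
})

test_that("patient volumes carry the exact inserted lesion", {
  g <- volume_grid(c(16, 16, 16), 2)
  base <- make_control_volume(g, 9)
  pv0 <- make_patient_volume(base, c(0, 0, 0), c(6, 5, 4), intensity_drop = 0)
  expect_identical(pv0$image$values, base$values)
  expect_gt(sum(pv0$lesion$values), 0)
  pv <- make_patient_volume(base, c(0, 0, 0), c(6, 5, 4), intensity_drop = 10)
  les <- pv$lesion$values
  expect_equal(pv$image$values[les], base$values[les] - 10)
  expect_identical(pv$image$values[!les], base$values[!les])
  expect_error(make_patient_volume(base, c(500, 0, 0), c(3, 3, 3), 10),
               "does not intersect")
})

test_that("behaviour generation reduces to the linear model without noise", {
  sp <- cohort_spec(n_patients = 4, n_controls = 2, noise_sd = 0,
                    b_age = 0, b_vol = 0,
                    effect_weights = list(global = c(slf3_right = 0),
                                          local = c(ifof_left = 0)),
                    baseline_scores = c(global = 80, local = 70))
  truth <- matrix(0, 4, 8, dimnames = list(NULL, names(default_tracts())))
  beh <- make_behaviour(truth, sp, rep(0, 4), rep("left", 4))
  expect_equal(beh$global_pct, rep(80, 4))
  expect_equal(beh$local_pct, rep(70, 4))
  # direct substitution: weight 5 on one tract, 2 cm^3 disconnection
  sp2 <- cohort_spec(n_patients = 1, n_controls = 2, noise_sd = 0,
                     b_age = 0, b_vol = 0,
                     effect_weights = list(global = c(slf3_right = 5),
                                           local = numeric(0)),
                     baseline_scores = c(global = 80, local = 70))
  truth2 <- matrix(0, 1, 8, dimnames = list(NULL, names(default_tracts())))
  truth2[1, "slf3_right"] <- 2
  beh2 <- make_behaviour(truth2, sp2, 0, "right")
  expect_equal(beh2$global_pct, 70)       # 80 - 5 * 2
  expect_equal(beh2$local_pct, 70)
})

test_that("scores are clipped to [0, 100] and monotone in disconnection", {
  sp <- cohort_spec(n_patients = 1, n_controls = 2, noise_sd = 0,
                    b_age = 0, b_vol = 0,
                    effect_weights = list(global = c(slf3_right = 50),
                                          local = numeric(0)),
                    baseline_scores = c(global = 90, local = 90))
  tr <- function(d) {
    m <- matrix(0, 1, 8, dimnames = list(NULL, names(default_tracts())))
    m[1, "slf3_right"] <- d
    m
  }
  scores <- sapply(c(0, 0.5, 1, 2, 5), function(d)
    make_behaviour(tr(d), sp, 0, "right")$global_pct)
  expect_true(all(scores >= 0 & scores <= 100))
  expect_true(all(diff(scores) <= 0))          # monotone decreasing
  expect_equal(scores[5], 0)                   # clipped at the floor
})

test_that("cohorts have the promised cardinalities and determinism", {
  co <- small_cohort()
  sp <- co$spec
  expect_equal(length(co$true_lesions), sp$n_patients)
  expect_equal(nrow(co$behaviour), sp$n_patients)
  expect_equal(nrow(co$truth), sp$n_patients)
  expect_true(all(co$behaviour$global_pct >= 0 & co$behaviour$global_pct <= 100))
  co2 <- generate_cohort(cohort_spec(n_patients = 15, n_controls = 5, seed = 11),
                         include_images = FALSE)
  expect_identical(co$behaviour, co2$behaviour)
  expect_identical(co$truth, co2$truth)
})

test_that("ground-truth disconnections equal measured overlaps voxel-exactly", {
  co <- small_cohort()
  tab <- build_disconnection_table(co$true_lesions, co$atlas, co$behaviour,
                                   threshold = co$spec$tract_threshold)
  for (tn in colnames(co$truth))
    expect_equal(tab[[paste0("disc_", tn)]], unname(co$truth[, tn]))
  # a lesion disjoint from a tract has zero truth
  cores <- lapply(co$atlas$maps, threshold_tract, threshold = co$spec$tract_threshold)
  for (i in seq_len(nrow(co$truth))) for (tn in colnames(co$truth))
    if (!any(co$true_lesions[[i]]$values & cores[[tn]]$values))
      expect_equal(co$truth[i, tn], 0)
})

test_that("cohorts round-trip through the on-disk layout", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_spec(grid = volume_grid(c(12, 12, 12), 2),
                                    n_patients = 3, n_controls = 2, seed = 5))
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "behaviour.tsv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  expect_true(file.exists(file.path(dir, "cohort_spec.yaml")))
  expect_equal(length(list.files(file.path(dir, "patients"))), 3)
  expect_equal(length(list.files(file.path(dir, "controls"))), 2)
  atlas <- read_tract_atlas(file.path(dir, "atlas", "manifest.yaml"))
  expect_equal(nrow(atlas$entries), nrow(co$atlas$entries))
  m1 <- atlas$maps[[1]]; m0 <- co$atlas$maps[[atlas$entries$name[1]]]
  expect_equal(m1$values, m0$values, tolerance = 1e-6)
  beh <- read.table(file.path(dir, "behaviour.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  expect_equal(beh$patient_id, co$behaviour$patient_id)
  expect_equal(beh$local_pct, co$behaviour$local_pct, tolerance = 1e-9)
})
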