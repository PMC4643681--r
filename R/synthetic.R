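#' Tract specification for the synthetic atlas
#'
#' Synthetic probabilistic tracts are tubes: the map value at a voxel is
#' `peak_probability * exp(-d^2 / (2 (radius_mm/2)^2))` where d is the
#' distance from the voxel centre to the tract's centerline (a polyline in
#' world mm). This mimics the shape of tractography-derived probability
#' maps: a high-probability core falling off towards a variable periphery.
#'
#' @param name Unique tract name (e.g. `"ifof_left"`).
#' @param hemisphere `"left"`, `"right"` or `"commissural"`.
#' @param centerline Numeric matrix (>= 2 rows x 3 columns) of world
#'   coordinates in mm.
#' @param radius_mm Tube radius parameter, > 0.
#' @param peak_probability Map value on the centerline, in (0, 1].
#' @return A `tract_spec` object.
#' @export
tract_spec <- function(name, hemisphere = c("left", "right", "commissural"),
                       centerline, radius_mm, peak_probability = 0.9) {
  hemisphere <- match.arg(hemisphere)
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 2L || ncol(centerline) != 3L)
    stop("'centerline' must be a matrix with >= 2 rows and 3 columns")
  if (!is.numeric(radius_mm) || radius_mm <= 0) stop("'radius_mm' must be > 0")
  if (peak_probability <= 0 || peak_probability > 1)
    stop("'peak_probability' must be in (0, 1]")
  structure(list(name = name, hemisphere = hemisphere, centerline = centerline,
                 radius_mm = radius_mm, peak_probability = peak_probability),
            class = "tract_spec")
}

#' Render a tract specification as a probability map
#'
#' @param spec A [tract_spec]; the centerline must lie inside the grid's
#'   bounding box.
#' @param grid A [volume_grid].
#' @return A [scalar_volume] with values in \[0, peak_probability\].
#' @export
make_tract_map <- function(spec, grid) {
  stopifnot(inherits(spec, "tract_spec"), inherits(grid, "volume_grid"))
  lo <- grid$origin_mm - grid$spacing_mm / 2
  hi <- grid$origin_mm + (grid$shape - 1) * grid$spacing_mm + grid$spacing_mm / 2
  for (ax in 1:3)
    if (any(spec$centerline[, ax] < lo[ax] | spec$centerline[, ax] > hi[ax]))
      stop(sprintf("centerline of '%s' leaves the grid bounding box on axis %d",
                   spec$name, ax))
  xs <- axis_coords(grid, 1); ys <- axis_coords(grid, 2); zs <- axis_coords(grid, 3)
  vx <- rep(xs, times = grid$shape[2] * grid$shape[3])
  vy <- rep(rep(ys, each = grid$shape[1]), times = grid$shape[3])
  vz <- rep(zs, each = grid$shape[1] * grid$shape[2])
  d2 <- rep(Inf, length(vx))
  for (s in seq_len(nrow(spec$centerline) - 1L)) {
    p <- spec$centerline[s, ]; q <- spec$centerline[s + 1L, ]
    seg <- q - p
    len2 <- sum(seg^2)
    tt <- if (len2 == 0) rep(0, length(vx)) else
      pmin(1, pmax(0, ((vx - p[1]) * seg[1] + (vy - p[2]) * seg[2] + (vz - p[3]) * seg[3]) / len2))
    d2 <- pmin(d2, (vx - (p[1] + tt * seg[1]))^2 +
                   (vy - (p[2] + tt * seg[2]))^2 +
                   (vz - (p[3] + tt * seg[3]))^2)
  }
  vals <- spec$peak_probability * exp(-d2 / (2 * (spec$radius_mm / 2)^2))
  scalar_volume(array(vals, grid$shape), grid)
}

#' Default synthetic tract set: the asymmetric scenario
#'
#' Four lateralized tract pairs on the given grid: inferior fronto-occipital
#' fasciculus (IFOF), superior longitudinal fasciculus III (SLF III), the
#' long segment of the perisylvian (arcuate) network, and the inferior
#' longitudinal fasciculus (ILF). In the default generating model the left
#' IFOF drives the local score and the right SLF III plus right long segment
#' drive the global score; the remaining tracts are inert, providing
#' negative controls for the regressions.
#'
#' @param grid A [volume_grid]; centerlines scale with the grid extents.
#' @return A named list of [tract_spec]s.
#' @export
default_tracts <- function(grid = volume_grid(c(32, 36, 32), 2)) {
  half <- (grid$shape - 1) * grid$spacing_mm / 2
  yl <- 0.72 * half[2]  # anterior-posterior reach of the tubes
  # lateral (x) and axial (z) positions scale with the grid so the same
  # scenario renders on any grid size; on the default grid they sit at
  # x ~ +/-14 (IFOF), +/-22 (SLF III), +/-15 (long segment), +/-24 (ILF)
  x1 <- 0.45 * half[1]; x2 <- 0.71 * half[1]; x3 <- 0.48 * half[1]
  x4 <- 0.77 * half[1]
  z1 <- -0.26 * half[3]; z2 <- 0.26 * half[3]; z3a <- 0.06 * half[3]
  z3b <- 0.45 * half[3]; z4 <- -0.39 * half[3]
  line <- function(x, z) cbind(c(x, x), c(-yl, yl), c(z, z))
  arc  <- function(x, zlo, zhi) cbind(c(x, x, x), c(-0.6 * yl, 0, 0.6 * yl), c(zlo, zhi, zlo))
  specs <- list(
    tract_spec("ifof_left",  "left",  line(-x1, z1), radius_mm = 7),
    tract_spec("ifof_right", "right", line(x1, z1),  radius_mm = 7),
    tract_spec("slf3_left",  "left",  line(-x2, z2), radius_mm = 7),
    tract_spec("slf3_right", "right", line(x2, z2),  radius_mm = 7),
    tract_spec("long_segment_left",  "left",  arc(-x3, z3a, z3b), radius_mm = 7),
    tract_spec("long_segment_right", "right", arc(x3, z3a, z3b),  radius_mm = 7),
    tract_spec("ilf_left",  "left",  line(-x4, z4), radius_mm = 5),
    tract_spec("ilf_right", "right", line(x4, z4),  radius_mm = 5)
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Cohort specification for the synthetic generator
#'
#' Collects every knob of the generative model. Behaviour is generated on
#' the percentage scale from a linear disconnection-to-deficit model:
#' \deqn{score = clip(baseline - \sum_t w_t d_t - b_{vol} V - b_{age}(age - \bar{age}) + \epsilon,\ 0,\ 100)}
#' with \eqn{d_t} the true overlap (cm^3) between the patient's lesion and
#' tract t's thresholded core, V the lesion volume in cm^3, and
#' \eqn{\epsilon \sim N(0, noise\_sd^2)}.
#'
#' @param grid Common [volume_grid] (default 32 x 36 x 32 voxels at 2 mm).
#' @param n_controls Number of control volumes, >= 2 (default 20).
#' @param n_patients Number of patients, >= 1 (default 60).
#' @param tracts Named list of [tract_spec]s (default [default_tracts()]).
#' @param effect_weights List with named numeric vectors `global` and
#'   `local`: deficit points per cm^3 of disconnection of each named tract.
#'   Every name must be a tract name.
#' @param baseline_scores Named vector `c(global =, local =)` in \[0, 100\]:
#'   expected score of a patient with no disconnection at the mean age.
#' @param noise_sd Behavioural noise sd in percentage points, >= 0.
#' @param age_mean,age_sd Age distribution (years).
#' @param b_age Deficit points per year of age above the mean.
#' @param b_vol Deficit points per cm^3 of total lesion volume.
#' @param lesion_size_range_mm Range from which each ellipsoid semi-axis is
#'   drawn uniformly.
#' @param intensity_drop Image-intensity reduction inside the lesion, in the
#'   arbitrary units of the control images (mean level 100, subject noise sd
#'   2), i.e. the default 20 is a 10-control-sd hypointensity.
#' @param effect_fraction Fraction of patients whose lesion is centred on a
#'   designated effect tract (the rest are placed at random).
#' @param tract_threshold Probability threshold defining each tract's core
#'   for the ground-truth disconnections (default 0.5).
#' @param seed Integer master seed; every draw derives from it.
#' @return A `cohort_spec` object (a validated list).
#' @export
cohort_spec <- function(grid = volume_grid(c(32, 36, 32), 2),
                        n_controls = 20, n_patients = 60,
                        tracts = default_tracts(grid),
                        effect_weights = list(
                          global = c(slf3_right = 15, long_segment_right = 15),
                          local  = c(ifof_left = 15)),
                        baseline_scores = c(global = 90, local = 90),
                        noise_sd = 5,
                        age_mean = 65, age_sd = 12,
                        b_age = 0.15, b_vol = 0.3,
                        lesion_size_range_mm = c(5, 12),
                        intensity_drop = 20,
                        effect_fraction = 0.6,
                        tract_threshold = 0.5,
                        seed = 1) {
  stopifnot(inherits(grid, "volume_grid"))
  if (n_controls < 2) stop("'n_controls' must be >= 2 (the control sd needs it)")
  if (n_patients < 1) stop("'n_patients' must be >= 1")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  tnames <- vapply(tracts, `[[`, "", "name")
  if (is.null(names(tracts))) names(tracts) <- tnames
  wn <- c(names(effect_weights$global), names(effect_weights$local))
  bad <- setdiff(wn, tnames)
  if (length(bad)) stop("effect_weights name tracts not in 'tracts': ",
                        paste(bad, collapse = ", "))
  if (any(baseline_scores < 0 | baseline_scores > 100))
    stop("'baseline_scores' must be in [0, 100]")
  if (any(lesion_size_range_mm <= 0) || length(lesion_size_range_mm) != 2L)
    stop("'lesion_size_range_mm' must be two positive numbers")
  if (effect_fraction < 0 || effect_fraction > 1)
    stop("'effect_fraction' must be in [0, 1]")
  structure(list(grid = grid, n_controls = as.integer(n_controls),
                 n_patients = as.integer(n_patients), tracts = tracts,
                 effect_weights = effect_weights,
                 baseline_scores = baseline_scores, noise_sd = noise_sd,
                 age_mean = age_mean, age_sd = age_sd, b_age = b_age,
                 b_vol = b_vol, lesion_size_range_mm = lesion_size_range_mm,
                 intensity_drop = intensity_drop,
                 effect_fraction = effect_fraction,
                 tract_threshold = tract_threshold,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Derived per-entity seed: one pseudo-random stream per patient/control so
# adding or removing subjects leaves the others' draws untouched.
#' @noRd
derive_seed <- function(seed, index, salt = 0L) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(index) * 97561 +
              as.numeric(salt) * 15485863) %% 2147483629)
}

#' Generate one control-like volume
#'
#' A smooth anatomical baseline (low-frequency field around an arbitrary
#' mean level of 100) shared by every subject on the same grid, plus
#' independent voxel noise specific to the subject. With a shared anatomy
#' the across-subject standard deviation at a voxel equals `noise_sd`, so a
#' lesion's contrast in control-sd units is `intensity_drop / noise_sd`.
#'
#' @param grid A [volume_grid].
#' @param seed Integer seed for the subject-specific noise.
#' @param mean_level Mean intensity (arbitrary units).
#' @param noise_sd Subject noise sd (default 2).
#' @param anatomy_seed Seed of the shared low-frequency anatomy pattern.
#' @return A [scalar_volume] with all values > 0.
#' @export
make_control_volume <- function(grid, seed, mean_level = 100, noise_sd = 2,
                                anatomy_seed = 760L) {
  stopifnot(inherits(grid, "volume_grid"))
  anat <- anatomy_field(grid, anatomy_seed)
  set.seed(as.integer(seed))
  vals <- anat + mean_level + stats::rnorm(prod(grid$shape), sd = noise_sd)
  scalar_volume(array(pmax(vals, 1e-3), grid$shape), grid)
}

# Shared low-frequency anatomy: smoothed white noise rescaled to sd 3,
# cached per (grid, seed) within the session.
#' @noRd
anatomy_field <- local({
  cache <- new.env(parent = emptyenv())
  function(grid, anatomy_seed) {
    key <- paste(c(grid$shape, grid$spacing_mm, grid$origin_mm, anatomy_seed),
                 collapse = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    set.seed(as.integer(anatomy_seed))
    raw <- scalar_volume(array(stats::rnorm(prod(grid$shape)), grid$shape), grid)
    sm <- gaussian_smooth(raw, fwhm_mm = 8 * mean(grid$spacing_mm))$values
    out <- sm / stats::sd(sm) * 3
    cache[[key]] <- out
    out
  }
})

#' Ellipsoid mask on a grid
#'
#' @param grid A [volume_grid].
#' @param center_mm World coordinate of the centre.
#' @param radii_mm Semi-axes (a, b, c) in mm; a scalar gives a sphere.
#' @return A [mask_volume] of the voxels whose centres satisfy
#'   `sum(((v - center) / radii)^2) <= 1`.
#' @export
ellipsoid_mask <- function(grid, center_mm, radii_mm) {
  if (length(radii_mm) == 1L) radii_mm <- rep(radii_mm, 3L)
  stopifnot(length(center_mm) == 3L, length(radii_mm) == 3L, all(radii_mm > 0))
  xs <- (axis_coords(grid, 1) - center_mm[1]) / radii_mm[1]
  ys <- (axis_coords(grid, 2) - center_mm[2]) / radii_mm[2]
  zs <- (axis_coords(grid, 3) - center_mm[3]) / radii_mm[3]
  q <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  mask_volume(q <= 1, grid)
}

#' Insert a hypointense lesion into a baseline volume
#'
#' Subtracts `intensity_drop` from every voxel inside the stated ellipsoid
#' and returns both the lesioned image and the exact ellipsoid mask as
#' ground truth.
#'
#' @param baseline A [scalar_volume] (e.g. from [make_control_volume()]).
#' @param lesion_center_mm,lesion_radii_mm Ellipsoid centre and semi-axes, mm.
#' @param intensity_drop Intensity reduction inside the lesion.
#' @return List with `image` ([scalar_volume]) and `lesion` ([mask_volume]).
#' @export
make_patient_volume <- function(baseline, lesion_center_mm, lesion_radii_mm,
                                intensity_drop) {
  stopifnot(inherits(baseline, "scalar_volume"))
  mask <- ellipsoid_mask(baseline$grid, lesion_center_mm, lesion_radii_mm)
  if (!any(mask$values))
    stop("lesion ellipsoid does not intersect the grid")
  vals <- baseline$values
  vals[mask$values] <- vals[mask$values] - intensity_drop
  list(image = scalar_volume(vals, baseline$grid), lesion = mask)
}

#' Generate behavioural scores from ground-truth disconnections
#'
#' Implements the generative model documented in [cohort_spec()]: a linear
#' deficit in the per-tract disconnections, total lesion volume and age,
#' plus Gaussian noise, clipped to \[0, 100\]. Ages, sex, handedness and
#' visual-field miss counts are drawn from per-patient streams derived from
#' the spec seed. Visual-field misses are Poisson with a rate increasing in
#' the contralateral lesion volume (left-field misses track right-hemisphere
#' damage and vice versa).
#'
#' @param truth Numeric matrix, patients x tracts, of true disconnection
#'   overlaps in cm^3; column names are tract names.
#' @param spec A [cohort_spec].
#' @param lesion_volume_cc Per-patient total lesion volume (cm^3).
#' @param lesion_side Per-patient lesion hemisphere, `"left"` or `"right"`.
#' @return A data.frame with columns `patient_id`, `global_pct`, `local_pct`,
#'   `age`, `sex`, `handedness`, `vf_miss_left`, `vf_miss_right`.
#' @export
make_behaviour <- function(truth, spec, lesion_volume_cc, lesion_side) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- nrow(truth)
  if (length(lesion_volume_cc) != n || length(lesion_side) != n)
    stop("'lesion_volume_cc' and 'lesion_side' must have one entry per truth row")
  missing_t <- setdiff(c(names(spec$effect_weights$global),
                         names(spec$effect_weights$local)), colnames(truth))
  if (length(missing_t))
    stop("truth matrix lacks columns for weighted tract(s): ",
         paste(missing_t, collapse = ", "))
  out <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                    global_pct = NA_real_, local_pct = NA_real_,
                    age = NA_real_, sex = NA_character_,
                    handedness = NA_character_,
                    vf_miss_left = NA_integer_, vf_miss_right = NA_integer_,
                    stringsAsFactors = FALSE)
  deficit <- function(weights, i) {
    if (length(weights) == 0) return(0)
    sum(weights * truth[i, names(weights)])
  }
  for (i in seq_len(n)) {
    set.seed(derive_seed(spec$seed, i, salt = 1L))
    age <- stats::rnorm(1, spec$age_mean, spec$age_sd)
    eps <- stats::rnorm(2, 0, spec$noise_sd)
    sex <- sample(c("F", "M"), 1)
    hand <- sample(c("right", "left"), 1, prob = c(0.9, 0.1))
    vf_l <- stats::rpois(1, 0.2 + 0.4 * lesion_volume_cc[i] * (lesion_side[i] == "right"))
    vf_r <- stats::rpois(1, 0.2 + 0.4 * lesion_volume_cc[i] * (lesion_side[i] == "left"))
    common <- spec$b_vol * lesion_volume_cc[i] + spec$b_age * (age - spec$age_mean)
    out$global_pct[i] <- min(100, max(0, spec$baseline_scores[["global"]] -
      deficit(spec$effect_weights$global, i) - common + eps[1]))
    out$local_pct[i] <- min(100, max(0, spec$baseline_scores[["local"]] -
      deficit(spec$effect_weights$local, i) - common + eps[2]))
    out$age[i] <- age; out$sex[i] <- sex; out$handedness[i] <- hand
    out$vf_miss_left[i] <- vf_l; out$vf_miss_right[i] <- vf_r
  }
  out
}

#' Generate a complete synthetic cohort
#'
#' Produces everything the downstream pipeline consumes: control volumes, a
#' probabilistic tract atlas rendered from the spec's tracts, patient
#' volumes with inserted ellipsoidal lesions (and the exact lesion masks as
#' ground truth), a behaviour table generated from the true disconnections,
#' and the truth itself. A configurable fraction of lesions is centred on
#' the designated effect tracts (jittered along the centerline); the rest
#' are placed uniformly at random within the inner brain region, always
#' lateralized away from the midline.
#'
#' @param spec A [cohort_spec].
#' @param include_images If `FALSE`, skip synthesising control and patient
#'   intensity volumes (ground-truth lesions, atlas, truth and behaviour are
#'   still produced). Useful when only the tabular stages are under study.
#' @return A `synthetic_cohort` object: list with `grid`, `controls`,
#'   `patients`, `true_lesions`, `atlas` (a `tract_atlas`), `behaviour`,
#'   `truth` (patients x tracts cm^3 matrix), `lesion_side`, and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(), include_images = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  grid <- spec$grid
  maps <- lapply(spec$tracts, make_tract_map, grid = grid)
  atlas <- tract_atlas(
    names = vapply(spec$tracts, `[[`, "", "name"),
    hemispheres = vapply(spec$tracts, `[[`, "", "hemisphere"),
    categories = rep("association", length(spec$tracts)),
    maps = maps)
  cores <- lapply(maps, threshold_tract, threshold = spec$tract_threshold)
  designated <- unique(c(names(spec$effect_weights$global),
                         names(spec$effect_weights$local)))
  half <- (grid$shape - 1) * grid$spacing_mm / 2
  n <- spec$n_patients
  true_lesions <- vector("list", n)
  lesion_side <- character(n)
  truth <- matrix(0, n, length(spec$tracts),
                  dimnames = list(sprintf("P%03d", seq_len(n)), names(spec$tracts)))
  for (i in seq_len(n)) {
    set.seed(derive_seed(spec$seed, i, salt = 0L))
    radii <- stats::runif(3, spec$lesion_size_range_mm[1], spec$lesion_size_range_mm[2])
    if (length(designated) && stats::runif(1) < spec$effect_fraction) {
      # cycle designated tracts by patient index so each is hit by a
      # comparable share of the effect patients
      tname <- designated[[(i - 1L) %% length(designated) + 1L]]
      cl <- spec$tracts[[tname]]$centerline
      # uniform position along the polyline (length-weighted segment choice)
      seg_len <- sqrt(rowSums((cl[-1, , drop = FALSE] - cl[-nrow(cl), , drop = FALSE])^2))
      s <- sample.int(length(seg_len), 1, prob = seg_len)
      u <- stats::runif(1)
      v <- cl[s, ] + u * (cl[s + 1L, ] - cl[s, ])
      center <- v + stats::rnorm(3, 0, 2)
      # keep the jittered centre inside the hemisphere it targets
      center[1] <- sign(v[1]) * max(abs(center[1]), 4)
    } else {
      center <- stats::runif(3, -0.7 * half, 0.7 * half)
      center[1] <- sign(center[1]) * max(abs(center[1]), 6)
    }
    center <- pmin(pmax(center, -0.85 * half), 0.85 * half)
    mask <- ellipsoid_mask(grid, center, radii)
    true_lesions[[i]] <- mask
    lesion_side[i] <- if (center[1] < 0) "left" else "right"
    for (tn in names(cores)) truth[i, tn] <- overlap_cc(mask, cores[[tn]])
  }
  lesion_vol <- vapply(true_lesions, volume_cc, 0)
  behaviour <- make_behaviour(truth, spec, lesion_vol, lesion_side)
  controls <- patients <- NULL
  if (include_images) {
    controls <- lapply(seq_len(spec$n_controls), function(j)
      make_control_volume(grid, derive_seed(spec$seed, j, salt = 3L)))
    patients <- vector("list", n)
    for (i in seq_len(n)) {
      base <- make_control_volume(grid, derive_seed(spec$seed, i, salt = 2L))
      vals <- base$values
      vals[true_lesions[[i]]$values] <- vals[true_lesions[[i]]$values] - spec$intensity_drop
      patients[[i]] <- scalar_volume(vals, grid)
    }
    names(patients) <- behaviour$patient_id
  }
  names(true_lesions) <- behaviour$patient_id
  structure(list(grid = grid, controls = controls, patients = patients,
                 true_lesions = true_lesions, atlas = atlas,
                 behaviour = behaviour, truth = truth,
                 lesion_side = lesion_side, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d controls%s, %d tracts on ",
              x$spec$n_patients, x$spec$n_controls,
              if (is.null(x$controls)) " (images not rendered)" else "",
              length(x$spec$tracts)))
  print(x$grid)
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' Lays the cohort out as files: `controls/ctrl_###.nii.gz`,
#' `patients/pat_###.nii.gz`, `lesions/P###.nii.gz` (ground truth),
#' `atlas/<tract>.nii.gz` plus `atlas/manifest.yaml`, `behaviour.tsv`,
#' `truth.json` and `cohort_spec.yaml` (a summary of the generating
#' parameters; tract geometry is kept in the manifest).
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  for (sub in c("", "controls", "patients", "lesions", "atlas"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cohort$controls))
    for (j in seq_along(cohort$controls))
      write_volume(cohort$controls[[j]],
                   file.path(dir, "controls", sprintf("ctrl_%03d.nii.gz", j)))
  if (!is.null(cohort$patients))
    for (id in names(cohort$patients))
      write_volume(cohort$patients[[id]],
                   file.path(dir, "patients", paste0(id, ".nii.gz")))
  for (id in names(cohort$true_lesions))
    write_volume(cohort$true_lesions[[id]],
                 file.path(dir, "lesions", paste0(id, ".nii.gz")))
  manifest <- list(tracts = lapply(seq_len(nrow(cohort$atlas$entries)), function(k) {
    e <- cohort$atlas$entries[k, ]
    list(name = e$name, hemisphere = e$hemisphere, category = e$category,
         file = paste0(e$name, ".nii.gz"))  # relative to the manifest
  }))
  for (k in seq_len(nrow(cohort$atlas$entries))) {
    nm <- cohort$atlas$entries$name[k]
    write_volume(cohort$atlas$maps[[nm]], file.path(dir, "atlas", paste0(nm, ".nii.gz")))
  }
  yaml::write_yaml(manifest, file.path(dir, "atlas", "manifest.yaml"))
  utils::write.table(cohort$behaviour, file.path(dir, "behaviour.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(weights = cohort$spec$effect_weights,
         disconnection_cc = as.data.frame(cohort$truth)),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  sp <- cohort$spec
  yaml::write_yaml(list(
    grid = list(shape = sp$grid$shape, spacing_mm = sp$grid$spacing_mm,
                origin_mm = sp$grid$origin_mm),
    n_controls = sp$n_controls, n_patients = sp$n_patients,
    baseline_scores = as.list(sp$baseline_scores), noise_sd = sp$noise_sd,
    age_mean = sp$age_mean, age_sd = sp$age_sd, b_age = sp$b_age,
    b_vol = sp$b_vol, lesion_size_range_mm = sp$lesion_size_range_mm,
    intensity_drop = sp$intensity_drop, effect_fraction = sp$effect_fraction,
    tract_threshold = sp$tract_threshold, seed = sp$seed),
    file.path(dir, "cohort_spec.yaml"))
  invisible(dir)
}
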