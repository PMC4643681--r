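#' The canonical 16-tract registry
#'
#' The tract-wise analyses consider 16 white-matter pathways: 10 association
#' (inferior longitudinal fasciculus, inferior fronto-occipital fasciculus,
#' the anterior, posterior and long segments of the perisylvian network,
#' cingulum, uncinate, and superior longitudinal fasciculus segments I-III),
#' 2 commissural (anterior commissure, corpus callosum) and 4 projection
#' (fornix, internal capsule, optic radiations, cortico-spinal tract). This
#' count fixes the default Bonferroni correction (family alpha / 16).
#'
#' @return A data.frame with columns `name` and `category`, 16 rows.
#' @export
canonical_tracts <- function() {
  data.frame(
    name = c("inferior_longitudinal_fasciculus",
             "inferior_fronto_occipital_fasciculus",
             "perisylvian_anterior_segment",
             "perisylvian_posterior_segment",
             "perisylvian_long_segment",
             "cingulum", "uncinate",
             "slf_1", "slf_2", "slf_3",
             "anterior_commissure", "corpus_callosum",
             "fornix", "internal_capsule", "optic_radiations",
             "cortico_spinal_tract"),
    category = c(rep("association", 10), rep("commissural", 2),
                 rep("projection", 4)),
    stringsAsFactors = FALSE)
}

#' Assemble a probabilistic tract atlas
#'
#' An atlas is a set of named probability maps on one grid. Map values are
#' interpreted as the probability of tract membership; atlases distributed
#' on a 0-100 percent scale (any value > 1) are normalised to \[0, 1\] with a
#' warning.
#'
#' @param names Character vector of unique tract names.
#' @param hemispheres `"left"`, `"right"` or `"commissural"`, per tract.
#' @param categories `"association"`, `"commissural"` or `"projection"`.
#' @param maps List of [scalar_volume]s, one per tract, on a common grid.
#' @return A `tract_atlas`: list with `entries` (data.frame: name,
#'   hemisphere, category) and `maps` (named list of [scalar_volume]).
#' @export
tract_atlas <- function(names, hemispheres, categories, maps) {
  if (anyDuplicated(names)) stop("tract names must be unique")
  n <- length(names)
  if (length(hemispheres) != n || length(categories) != n || length(maps) != n)
    stop("'names', 'hemispheres', 'categories' and 'maps' must align")
  if (!all(hemispheres %in% c("left", "right", "commissural")))
    stop("hemispheres must be left/right/commissural")
  if (!all(categories %in% c("association", "commissural", "projection")))
    stop("categories must be association/commissural/projection")
  grid <- assert_same_grid(maps)
  maps <- stats::setNames(lapply(seq_len(n), function(k) {
    m <- maps[[k]]
    mx <- max(m$values)
    if (mx > 1) {
      warning(sprintf("tract '%s': values exceed 1 (max %.3g); assuming percent scale, dividing by 100",
                      names[k], mx))
      m <- scalar_volume(m$values / 100, m$grid)
    }
    if (min(m$values) < 0) stop(sprintf("tract '%s': negative probabilities", names[k]))
    m
  }), names)
  structure(list(entries = data.frame(name = names, hemisphere = hemispheres,
                                      category = categories,
                                      stringsAsFactors = FALSE),
                 maps = maps, grid = grid),
            class = "tract_atlas")
}

#' @export
print.tract_atlas <- function(x, ...) {
  cat(sprintf("<tract_atlas> %d tracts (%s) on ", nrow(x$entries),
              paste(sprintf("%d %s", table(x$entries$category),
                            names(table(x$entries$category))), collapse = ", ")))
  print(x$grid)
  invisible(x)
}

#' Read a tract atlas from a manifest file
#'
#' The manifest is YAML with a top-level `tracts` list whose entries carry
#' `name`, `hemisphere`, `category` and `file` (NIfTI path relative to the
#' manifest's directory, or absolute).
#'
#' @param path Path to `manifest.yaml`.
#' @return A `tract_atlas`.
#' @export
read_tract_atlas <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such atlas manifest: '%s'", path))
  man <- yaml::read_yaml(path)
  if (is.null(man$tracts) || !length(man$tracts))
    stop(sprintf("manifest '%s' lists no tracts", path))
  base <- dirname(path)
  entries <- lapply(man$tracts, function(e) {
    for (f in c("name", "hemisphere", "category", "file"))
      if (is.null(e[[f]])) stop(sprintf("manifest entry missing field '%s'", f))
    e
  })
  files <- vapply(entries, function(e) {
    f <- e$file
    if (!file.exists(f)) f <- file.path(base, e$file)
    if (!file.exists(f)) stop(sprintf("atlas map not found: '%s'", e$file))
    f
  }, "")
  tract_atlas(names = vapply(entries, `[[`, "", "name"),
              hemispheres = vapply(entries, `[[`, "", "hemisphere"),
              categories = vapply(entries, `[[`, "", "category"),
              maps = lapply(files, read_volume))
}

#' Threshold a tract probability map to its anatomical core
#'
#' Keeps voxels whose membership probability is at least `threshold`
#' (inclusive). The default 50% follows the convention of considering only
#' the anatomical core of a tract, excluding its individually variable
#' periphery.
#'
#' @param map A [scalar_volume] with values in \[0, 1\].
#' @param threshold Probability cut-off in (0, 1), default 0.5.
#' @return A [mask_volume].
#' @export
threshold_tract <- function(map, threshold = 0.5) {
  stopifnot(inherits(map, "scalar_volume"))
  if (threshold <= 0 || threshold >= 1) stop("'threshold' must be in (0, 1)")
  mask_volume(map$values >= threshold, map$grid)
}

#' Lesion-tract overlap volume
#'
#' The continuous disconnection measure: the volume in cm^3 of the
#' intersection between a binary lesion map and a thresholded tract core.
#'
#' @param lesion,tract_mask [mask_volume]s on one grid.
#' @return Nonnegative scalar, cm^3.
#' @export
overlap_cc <- function(lesion, tract_mask) {
  stopifnot(inherits(lesion, "mask_volume"), inherits(tract_mask, "mask_volume"))
  assert_same_grid(list(lesion = lesion, tract = tract_mask))
  sum(lesion$values & tract_mask$values) * voxel_volume_mm3(lesion$grid) / 1000
}

#' Build the patients-by-tracts disconnection table
#'
#' For every patient and every atlas tract, measures the overlap (cm^3)
#' between the patient's lesion and the tract's thresholded core, recomputes
#' the lesion volume from the mask, and joins the behaviour table (scores
#' and covariates) by patient id.
#'
#' @param lesions Named list of [mask_volume]s; names are patient ids.
#' @param atlas A [tract_atlas].
#' @param behaviour Data.frame with a `patient_id` column plus outcomes and
#'   covariates; must cover exactly the lesion ids.
#' @param threshold Tract-core probability threshold, default 0.5.
#' @return A data.frame of class `disconnection_table`: `patient_id`,
#'   `lesion_volume_cc`, one `disc_<tract>` column per atlas entry (cm^3),
#'   then the behaviour columns. The tract column names are recorded in
#'   `attr(, "tract_cols")`.
#' @export
build_disconnection_table <- function(lesions, atlas, behaviour, threshold = 0.5) {
  stopifnot(inherits(atlas, "tract_atlas"))
  if (is.null(names(lesions)) || any(!nzchar(names(lesions))))
    stop("'lesions' must be a named list (patient ids)")
  if (!"patient_id" %in% names(behaviour))
    stop("'behaviour' needs a 'patient_id' column")
  if (!setequal(names(lesions), behaviour$patient_id))
    stop("patient ids in 'lesions' and 'behaviour' do not match")
  assert_same_grid(c(unname(lesions), list(atlas$grid)))
  cores <- lapply(atlas$maps, threshold_tract, threshold = threshold)
  ids <- behaviour$patient_id
  disc <- matrix(0, length(ids), nrow(atlas$entries),
                 dimnames = list(ids, paste0("disc_", atlas$entries$name)))
  vol <- numeric(length(ids))
  for (i in seq_along(ids)) {
    les <- lesions[[ids[i]]]
    vol[i] <- volume_cc(les)
    for (k in seq_along(cores))
      disc[i, k] <- overlap_cc(les, cores[[k]])
  }
  out <- cbind(data.frame(patient_id = ids, lesion_volume_cc = vol,
                          stringsAsFactors = FALSE),
               as.data.frame(disc),
               behaviour[match(ids, behaviour$patient_id),
                         setdiff(names(behaviour), "patient_id"), drop = FALSE])
  rownames(out) <- NULL
  attr(out, "tract_cols") <- colnames(disc)
  attr(out, "threshold") <- threshold
  class(out) <- c("disconnection_table", "data.frame")
  out
}

#' Percentage of patients disconnected, per tract
#'
#' A patient counts as disconnected in a tract when the overlap exceeds
#' `min_cc` (default 0: any shared voxel).
#'
#' @param table A `disconnection_table`.
#' @param min_cc Minimum overlap (cm^3) to count as disconnection.
#' @return Named numeric vector of percentages, one per tract.
#' @export
percent_disconnected <- function(table, min_cc = 0) {
  tract_cols <- attr(table, "tract_cols")
  if (is.null(tract_cols)) stop("'table' must come from build_disconnection_table()")
  if (nrow(table) == 0L) stop("empty disconnection table")
  out <- vapply(tract_cols, function(cl) 100 * mean(table[[cl]] > min_cc), 0)
  stats::setNames(out, sub("^disc_", "", tract_cols))
}

#' Group lesion-overlap map
#'
#' Counts, at every voxel, how many patients have a lesion there — the
#' standard descriptive map of a cohort's lesion distribution.
#'
#' @param lesions List of [mask_volume]s on one grid.
#' @return A [scalar_volume] of integer counts.
#' @export
group_lesion_overlap <- function(lesions) {
  if (!length(lesions)) stop("'lesions' must be nonempty")
  grid <- assert_same_grid(lesions)
  acc <- array(0, grid$shape)
  for (m in lesions) acc <- acc + m$values
  scalar_volume(acc, grid)
}
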