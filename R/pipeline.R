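#' Default pipeline configuration
#' @noRd
default_config <- function() {
  list(
    mode = "simulate",
    seed = 1L,
    cohort = list(
      shape = c(32L, 36L, 32L), spacing_mm = 2,
      n_controls = 20L, n_patients = 60L,
      baseline_global = 90, baseline_local = 90, noise_sd = 5,
      age_mean = 65, age_sd = 12, b_age = 0.15, b_vol = 0.3,
      lesion_size_min_mm = 5, lesion_size_max_mm = 12,
      intensity_drop = 20, effect_fraction = 0.6),
    paths = list(
      lesions_dir = NULL, atlas_manifest = NULL, behaviour = NULL,
      controls_dir = NULL, patients_dir = NULL),
    delineation = list(t_threshold = NULL, p = 0.01, tail = "hypointense",
                       min_cluster_voxels = 0L),
    disconnection = list(threshold = 0.5),
    trackwise = list(family_alpha = 0.05, n_tests = 16L, include_vf = TRUE),
    glm = list(enabled = TRUE, fwhm_mm = 12, voxel_p = 0.001,
               extent_mm3 = 800, n_perm = 200L, connectivity = 26L),
    log_level = "info")
}

# Merge user values over defaults, rejecting unknown keys with a suggestion.
#' @noRd
merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      cand <- agrep(key, names(defaults), max.distance = 2, value = TRUE)
      hint <- if (length(cand)) sprintf("; did you mean '%s'?", cand[1]) else ""
      stop(sprintf("unknown config key '%s'%s", here, hint))
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop(sprintf("config key '%s' must be a mapping", here))
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration, fills every omitted key with its documented
#' default, rejects unknown keys (with a closest-match suggestion, so typos
#' like `n_patient` fail loudly), and checks the schema: one of the two
#' modes, positive sizes, referenced paths present in ingest mode.
#'
#' @param path Path to a YAML file, or a named list of overrides (handy in
#'   scripts).
#' @return A validated `pipeline_config` (a nested list).
#' @export
validate_config <- function(path = list()) {
  user <- if (is.character(path)) {
    if (!file.exists(path)) stop(sprintf("no such config file: '%s'", path))
    yaml::read_yaml(path)
  } else if (is.list(path)) path else stop("'path' must be a file path or a list")
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user)
  if (!cfg$mode %in% c("simulate", "ingest"))
    stop("config key 'mode' must be 'simulate' or 'ingest'")
  co <- cfg$cohort
  for (key in c("n_controls", "n_patients")) {
    if (!is.numeric(co[[key]]) || length(co[[key]]) != 1L || co[[key]] < 1)
      stop(sprintf("config key 'cohort.%s' must be a positive integer", key))
  }
  if (co$n_controls < 2) stop("config key 'cohort.n_controls' must be >= 2")
  if (co$noise_sd < 0) stop("config key 'cohort.noise_sd' must be >= 0")
  if (cfg$glm$n_perm < 100) stop("config key 'glm.n_perm' must be >= 100")
  if (cfg$mode == "ingest") {
    for (key in c("lesions_dir", "atlas_manifest", "behaviour")) {
      p <- cfg$paths[[key]]
      if (is.null(p)) stop(sprintf("ingest mode requires config key 'paths.%s'", key))
      if (!file.exists(p)) stop(sprintf("config key 'paths.%s': no such path '%s'", key, p))
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @noRd
cohort_spec_from_config <- function(cfg) {
  co <- cfg$cohort
  grid <- volume_grid(co$shape, co$spacing_mm)
  cohort_spec(grid = grid, n_controls = co$n_controls, n_patients = co$n_patients,
              baseline_scores = c(global = co$baseline_global, local = co$baseline_local),
              noise_sd = co$noise_sd, age_mean = co$age_mean, age_sd = co$age_sd,
              b_age = co$b_age, b_vol = co$b_vol,
              lesion_size_range_mm = c(co$lesion_size_min_mm, co$lesion_size_max_mm),
              intensity_drop = co$intensity_drop,
              effect_fraction = co$effect_fraction,
              tract_threshold = cfg$disconnection$threshold,
              seed = cfg$seed)
}

#' Run the full lesion-symptom mapping pipeline
#'
#' One call from cohort to report: simulate a synthetic cohort (or ingest
#' lesion maps, an atlas manifest and a behaviour table), delineate lesions
#' from patient images when controls are available, build the disconnection
#' table, run the track-wise regressions for both outcomes and both
#' covariate models, optionally run the voxel-wise GLM with permutation
#' cluster correction on smoothed lesion maps, and write every stage's
#' output plus a JSON report and a log to `out_dir`. All randomness derives
#' from `config$seed`, so a rerun with the same configuration reproduces
#' every table byte for byte.
#'
#' @param config A `pipeline_config` from [validate_config()] (or anything
#'   it accepts: a YAML path or a list of overrides).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the main in-memory products: `table`
#'   (disconnection table), `trackwise` (all regression results),
#'   `clusters` (per outcome), `report`.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  t0 <- proc.time()[["elapsed"]]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                 file = log_path, append = TRUE)
  cat("", file = log_path)
  report <- list(mode = config$mode, seed = config$seed)

  if (config$mode == "simulate") {
    spec <- cohort_spec_from_config(config)
    logf("stage simulate: %d patients, %d controls, %d tracts",
         spec$n_patients, spec$n_controls, length(spec$tracts))
    cohort <- generate_cohort(spec, include_images = TRUE)
    atlas <- cohort$atlas
    behaviour <- cohort$behaviour
    ref <- fit_control_reference(cohort$controls)
    patients <- cohort$patients
    lesions <- NULL
  } else {
    atlas <- read_tract_atlas(config$paths$atlas_manifest)
    behaviour <- utils::read.table(config$paths$behaviour, header = TRUE,
                                   sep = "\t", stringsAsFactors = FALSE)
    files <- list.files(config$paths$lesions_dir, "\\.nii(\\.gz)?$",
                        full.names = TRUE)
    if (!length(files))
      stop(sprintf("stage ingest: no NIfTI lesion maps in '%s'",
                   config$paths$lesions_dir))
    lesions <- lapply(files, read_volume, as_mask = TRUE)
    names(lesions) <- sub("\\.nii(\\.gz)?$", "", basename(files))
    logf("stage ingest: %d lesion maps, %d behaviour rows, %d tracts",
         length(lesions), nrow(behaviour), nrow(atlas$entries))
    patients <- ref <- NULL
  }

  # -- delineation (when patient images and controls exist) ----------------
  if (!is.null(patients) && !is.null(ref)) {
    thr <- config$delineation$t_threshold
    if (is.null(thr)) thr <- auto_t_threshold(ref$n, config$delineation$p)
    lesions <- vector("list", length(patients))
    names(lesions) <- names(patients)
    degen <- 0L
    for (id in names(patients)) {
      d <- delineate(patients[[id]], ref, t_threshold = thr,
                     tail = config$delineation$tail,
                     min_cluster_voxels = config$delineation$min_cluster_voxels)
      lesions[[id]] <- d$mask
      degen <- max(degen, d$report$degenerate_voxels)
    }
    dir.create(file.path(out_dir, "lesions"), showWarnings = FALSE)
    for (id in names(lesions))
      write_volume(lesions[[id]], file.path(out_dir, "lesions", paste0(id, ".nii.gz")))
    logf("stage delineate: t threshold %.3f (df %d), %d masks written, %d degenerate voxels",
         thr, ref$n - 1L, length(lesions), degen)
    report$delineation <- list(t_threshold = thr, df = ref$n - 1L,
                               degenerate_voxels = degen)
  }

  # -- disconnection table -------------------------------------------------
  tab <- build_disconnection_table(lesions, atlas, behaviour,
                                   threshold = config$disconnection$threshold)
  write_tsv(tab, file.path(out_dir, "disconnection_table.tsv"))
  logf("stage disconnect: %d patients x %d tracts, threshold %.2f",
       nrow(tab), nrow(atlas$entries), config$disconnection$threshold)

  # -- track-wise regressions ----------------------------------------------
  alpha <- bonferroni_alpha(config$trackwise$n_tests, config$trackwise$family_alpha)
  models <- if (isTRUE(config$trackwise$include_vf)) c(FALSE, TRUE) else FALSE
  tw <- list(); skipped <- NULL
  for (outc in c("global_pct", "local_pct")) for (vf in models) {
    r <- run_trackwise_analysis(tab, atlas, outc, include_vf = vf)
    skipped <- rbind(skipped, attr(r, "skipped"))
    tw[[length(tw) + 1L]] <- flag_significant(r, alpha)
  }
  tw <- do.call(rbind, tw)
  write_tsv(tw, file.path(out_dir, "trackwise_results.tsv"))
  logf("stage trackwise: %d fits, %d significant at alpha %.6f, %d skips",
       nrow(tw), sum(tw$significant), alpha,
       if (is.null(skipped)) 0L else nrow(skipped))
  report$trackwise <- list(corrected_alpha = alpha, n_fits = nrow(tw),
                           n_significant = sum(tw$significant),
                           skipped = if (is.null(skipped)) list() else unique(skipped))

  # -- voxel-wise GLM on smoothed lesion maps ------------------------------
  clusters <- list()
  if (isTRUE(config$glm$enabled)) {
    smoothed <- lapply(tab$patient_id, function(id) {
      m <- lesions[[id]]
      gaussian_smooth(scalar_volume(array(as.numeric(m$values), m$grid$shape),
                                    m$grid), config$glm$fwhm_mm)
    })
    X <- design_matrix(tab)
    for (outc in c("global_pct", "local_pct")) {
      cv <- contrast_vector(X, outc, sign = -1)  # deficit direction
      cl <- permutation_cluster_p(smoothed, X, cv,
                                  n_perm = config$glm$n_perm,
                                  seed = derive_seed(config$seed, 0L, salt = 9L),
                                  voxel_p = config$glm$voxel_p,
                                  extent_mm3 = config$glm$extent_mm3,
                                  connectivity = config$glm$connectivity)
      clusters[[outc]] <- cl
      write_tsv(cl, file.path(out_dir, sprintf("clusters_%s.tsv",
                                               sub("_pct$", "", outc))))
      logf("stage glm (%s): %d cluster(s) past %g mm^3, min cluster p %s",
           outc, nrow(cl), config$glm$extent_mm3,
           if (nrow(cl)) format(min(cl$cluster_p)) else "-")
    }
    report$glm <- list(fwhm_mm = config$glm$fwhm_mm,
                       voxel_p = config$glm$voxel_p,
                       extent_mm3 = config$glm$extent_mm3,
                       n_perm = config$glm$n_perm,
                       n_clusters = vapply(clusters, nrow, 0L))
  }

  report$n_patients <- nrow(tab)
  report$runtime_s <- round(proc.time()[["elapsed"]] - t0, 2)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  logf("pipeline done in %.1f s", report$runtime_s)
  invisible(list(table = tab, trackwise = tw, clusters = clusters,
                 report = report))
}

#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}
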