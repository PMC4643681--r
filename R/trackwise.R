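#' Per-tract lesion-deficit regression
#'
#' Ordinary least squares of a behavioural outcome on one tract's
#' disconnection measure plus covariates — always lesion volume and age,
#' optionally the left and right visual-field miss counts (the control
#' model). The coefficient of interest is reported standardized,
#' `beta_std = slope * sd(disconnection) / sd(outcome)`, with the two-sided
#' p-value of its t test.
#'
#' @param table A `disconnection_table` from [build_disconnection_table()].
#' @param tract Tract name (without the `disc_` prefix).
#' @param outcome `"global_pct"` or `"local_pct"` (any numeric column works).
#' @param include_vf Add `vf_miss_left` and `vf_miss_right` as covariates.
#' @param hemisphere Optional tag carried into the result (no subsetting is
#'   done here; hemisphere assignment of tracts happens in
#'   [run_trackwise_analysis()]).
#' @return A one-row data.frame: `tract`, `hemisphere`, `outcome`, `n`,
#'   `beta_std`, `p_value`, `covariates`.
#' @export
fit_tract_regression <- function(table, tract, outcome = c("local_pct", "global_pct"),
                                 include_vf = FALSE, hemisphere = NA_character_) {
  outcome <- if (length(outcome) > 1L) match.arg(outcome) else outcome
  dcol <- paste0("disc_", tract)
  if (!dcol %in% names(table)) stop(sprintf("no disconnection column for tract '%s'", tract))
  if (!outcome %in% names(table)) stop(sprintf("no outcome column '%s'", outcome))
  covars <- c("lesion_volume_cc", "age")
  if (include_vf) covars <- c(covars, "vf_miss_left", "vf_miss_right")
  miss <- setdiff(covars, names(table))
  if (length(miss)) stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  cols <- c(outcome, dcol, covars)
  dat <- table[, cols]
  complete <- stats::complete.cases(dat)
  dropped <- sum(!complete)
  dat <- dat[complete, ]
  if (nrow(dat) <= length(covars) + 2L)
    stop("too few complete rows to fit the model")
  for (cl in c(dcol, covars))
    if (stats::sd(dat[[cl]]) == 0)
      stop(sprintf("zero-variance predictor '%s'", cl))
  fml <- stats::reformulate(c(dcol, covars), response = outcome)
  fit <- stats::lm(fml, data = dat)
  if (fit$rank < length(covars) + 2L)
    stop("collinear design; dropped coefficient(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  sm <- summary(fit)$coefficients
  slope <- sm[dcol, "Estimate"]
  res <- data.frame(tract = tract, hemisphere = hemisphere, outcome = outcome,
                    n = nrow(dat),
                    beta_std = slope * stats::sd(dat[[dcol]]) / stats::sd(dat[[outcome]]),
                    p_value = sm[dcol, "Pr(>|t|)"],
                    covariates = paste(covars, collapse = "+"),
                    stringsAsFactors = FALSE)
  attr(res, "rows_dropped") <- dropped
  res
}

#' Run the track-wise lesion-deficit analysis
#'
#' One regression per tract and hemisphere: lateralized tracts are fitted
#' within their own hemisphere run; commissural tracts are included in both
#' runs (configurable via `commissural`). Tracts never overlapped by any
#' lesion have a zero-variance disconnection predictor; they are reported as
#' skipped rather than fitted. Note that skipping does not shrink the
#' Bonferroni family — the corrected alpha is fixed by `n_tests` in
#' [flag_significant()]/[bonferroni_alpha()], conventionally the full atlas
#' count of 16.
#'
#' @param table A `disconnection_table`.
#' @param atlas The [tract_atlas] the table was built from (supplies
#'   hemisphere tags).
#' @param outcome `"global_pct"` or `"local_pct"`.
#' @param include_vf Add the visual-field covariates to every design.
#' @param hemispheres Which hemisphere runs to perform.
#' @param commissural `"both"` (default: commissural tracts enter both
#'   hemisphere runs) or `"skip"`.
#' @return A data.frame of fitted results (columns as in
#'   [fit_tract_regression()]), with skipped tracts in
#'   `attr(, "skipped")` (tract, hemisphere, reason).
#' @export
run_trackwise_analysis <- function(table, atlas, outcome = c("local_pct", "global_pct"),
                                   include_vf = FALSE,
                                   hemispheres = c("left", "right"),
                                   commissural = c("both", "skip")) {
  outcome <- if (length(outcome) > 1L) match.arg(outcome) else outcome
  commissural <- match.arg(commissural)
  stopifnot(inherits(atlas, "tract_atlas"))
  results <- list(); skipped <- list()
  for (h in hemispheres) {
    sel <- atlas$entries$hemisphere == h |
      (commissural == "both" & atlas$entries$hemisphere == "commissural")
    for (tr in atlas$entries$name[sel]) {
      x <- table[[paste0("disc_", tr)]]
      if (is.null(x)) stop(sprintf("table lacks column disc_%s", tr))
      if (all(x == 0) || stats::sd(x, na.rm = TRUE) == 0) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          tract = tr, hemisphere = h,
          reason = "no lesion overlaps this tract (zero-variance predictor)",
          stringsAsFactors = FALSE)
        next
      }
      results[[length(results) + 1L]] <-
        fit_tract_regression(table, tr, outcome, include_vf, hemisphere = h)
    }
  }
  out <- if (length(results)) do.call(rbind, results) else
    data.frame(tract = character(), hemisphere = character(),
               outcome = character(), n = integer(), beta_std = numeric(),
               p_value = numeric(), covariates = character())
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  out
}

#' Bonferroni-corrected alpha level
#'
#' `family_alpha / n_tests`. With the canonical 16-tract family and family
#' alpha 0.05 this is 0.003125, conventionally printed as .003; the package
#' always applies the unrounded value, so an observed p of exactly 0.003
#' counts as significant.
#'
#' @param n_tests Number of tests in the family (>= 1), default 16.
#' @param family_alpha Family-wise error rate, in (0, 1).
#' @return The per-test alpha.
#' @examples
#' bonferroni_alpha(16, 0.05)  # 0.003125
#' @export
bonferroni_alpha <- function(n_tests = 16, family_alpha = 0.05) {
  if (!is.numeric(n_tests) || length(n_tests) != 1L || n_tests < 1)
    stop("'n_tests' must be a single integer >= 1")
  if (family_alpha <= 0 || family_alpha >= 1)
    stop("'family_alpha' must be in (0, 1)")
  family_alpha / n_tests
}

#' Flag Bonferroni-surviving results
#'
#' Adds a logical `significant` column: `p_value < corrected_alpha`
#' (strict). Ordering and all fitted quantities are untouched.
#'
#' @param results Data.frame with a `p_value` column (as returned by
#'   [run_trackwise_analysis()]).
#' @param corrected_alpha The per-test alpha, e.g. from [bonferroni_alpha()].
#' @return `results` with a `significant` column appended.
#' @export
flag_significant <- function(results, corrected_alpha = bonferroni_alpha()) {
  if (!"p_value" %in% names(results)) stop("'results' needs a 'p_value' column")
  results$significant <- results$p_value < corrected_alpha
  results
}
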