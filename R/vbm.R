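#' Standard design matrix for the voxel-wise GLM
#'
#' Builds the numeric design used by the simplified voxel-wise analysis:
#' intercept, global and local percentage scores as the covariates of
#' interest, and age, sex, handedness and lesion volume as confound
#' covariates. Sex and handedness are coded 0/1 (`M` = 1, `right` = 1).
#'
#' @param table A data.frame with columns `global_pct`, `local_pct`, `age`,
#'   `sex`, `handedness`, `lesion_volume_cc` (e.g. a `disconnection_table`).
#' @return A numeric matrix with named columns, one row per patient.
#' @export
design_matrix <- function(table) {
  need <- c("global_pct", "local_pct", "age", "sex", "handedness", "lesion_volume_cc")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing design column(s): ", paste(miss, collapse = ", "))
  X <- cbind(intercept = 1,
             global_pct = table$global_pct,
             local_pct = table$local_pct,
             age = table$age,
             sex = as.numeric(table$sex == "M"),
             handedness = as.numeric(table$handedness == "right"),
             lesion_volume_cc = table$lesion_volume_cc)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient (a covariate is constant or collinear)")
  X
}

#' Contrast vector for one design column
#'
#' @param design A design matrix with column names.
#' @param column Column to test.
#' @param sign +1 or -1 (direction of the one-sided test downstream).
#' @return Numeric contrast vector of length `ncol(design)`.
#' @export
contrast_vector <- function(design, column, sign = 1) {
  if (!column %in% colnames(design)) stop(sprintf("no design column '%s'", column))
  cv <- stats::setNames(numeric(ncol(design)), colnames(design))
  cv[column] <- sign
  cv
}

# Core mass-univariate OLS: Y is n x V, X is n x p; returns the t statistic
# of contrast %*% beta at every voxel (0 where the residual variance is 0).
#' @noRd
glm_t_values <- function(Y, X, contrast) {
  n <- nrow(X); p <- ncol(X)
  XtXi <- chol2inv(chol(crossprod(X)))
  B <- XtXi %*% crossprod(X, Y)            # p x V
  res <- Y - X %*% B
  rss <- colSums(res^2)
  df <- n - p
  sigma2 <- rss / df
  cvar <- drop(t(contrast) %*% XtXi %*% contrast)
  num <- drop(t(contrast) %*% B)
  # zero residual variance relative to the voxel's data energy (covers the
  # perfect-fit limit, where every rss is rounding noise)
  zero <- rss <= 1e-10 * pmax(colSums(Y^2), .Machine$double.xmin)
  tt <- num / sqrt(pmax(sigma2, .Machine$double.eps) * cvar)
  tt[zero] <- 0
  list(t = tt, df = df, zero_variance = sum(zero))
}

#' Mass-univariate voxel-wise GLM
#'
#' Fits the same ordinary-least-squares model at every voxel of a set of
#' patient images (already smoothed upstream) and returns the t-statistic
#' map of the requested contrast. In the synthetic pipeline the "images" are
#' smoothed lesion masks — a lesion-density stand-in for segmented tissue
#' maps that preserves the inference structure of a voxel-based analysis.
#'
#' @param images List of [scalar_volume]s on one grid, one per design row.
#' @param design Numeric design matrix (see [design_matrix()]); full column
#'   rank required.
#' @param contrast Numeric vector of length `ncol(design)`, not all zero.
#' @return A [scalar_volume] of t values with attributes `df` and
#'   `zero_variance_voxels`.
#' @export
fit_voxelwise_glm <- function(images, design, contrast) {
  grid <- assert_same_grid(images)
  design <- as.matrix(design)
  if (length(images) != nrow(design))
    stop("number of images and design rows differ")
  if (length(contrast) != ncol(design))
    stop("contrast length must equal the number of design columns")
  if (all(contrast == 0)) stop("contrast must not be all zeros")
  if (qr(design)$rank < ncol(design)) stop("design matrix is rank deficient")
  Y <- do.call(rbind, lapply(images, function(v) as.vector(v$values)))
  g <- glm_t_values(Y, design, contrast)
  out <- scalar_volume(array(g$t, grid$shape), grid)
  attr(out, "df") <- g$df
  attr(out, "zero_variance_voxels") <- g$zero_variance
  out
}

#' Suprathreshold clusters of a t map
#'
#' Thresholds the map at the t value of one-sided `voxel_p` at `df` degrees
#' of freedom (the cluster-forming threshold), labels connected components,
#' and discards components smaller than the extent threshold. On a 2 mm
#' isotropic grid the default 800 mm^3 extent corresponds to 100 voxels.
#'
#' @param tmap A [scalar_volume] of t values.
#' @param df Degrees of freedom (taken from `attr(tmap, "df")` if missing).
#' @param voxel_p One-sided cluster-forming p threshold, default 0.001.
#' @param extent_mm3 Minimum cluster volume retained, default 800.
#' @param connectivity 6, 18 or 26 (default).
#' @param two_sided If `TRUE`, threshold |t| (at `voxel_p`, still one tail
#'   per sign) so deficit- and sparing-direction clusters both appear.
#' @return A data.frame with one row per cluster (largest first):
#'   `size_voxels`, `size_mm3`, `peak_stat`, `peak_x_mm`, `peak_y_mm`,
#'   `peak_z_mm`, `cluster_p` (NA here; filled by
#'   [permutation_cluster_p()]).
#' @export
extract_clusters <- function(tmap, df = attr(tmap, "df"), voxel_p = 0.001,
                             extent_mm3 = 800, connectivity = 26,
                             two_sided = FALSE) {
  stopifnot(inherits(tmap, "scalar_volume"))
  if (is.null(df) || df < 1) stop("'df' must be >= 1")
  if (voxel_p <= 0 || voxel_p >= 1) stop("'voxel_p' must be in (0, 1)")
  t_crit <- stats::qt(1 - voxel_p, df)
  sel <- if (two_sided) abs(tmap$values) >= t_crit else tmap$values >= t_crit
  empty <- data.frame(size_voxels = integer(), size_mm3 = numeric(),
                      peak_stat = numeric(), peak_x_mm = numeric(),
                      peak_y_mm = numeric(), peak_z_mm = numeric(),
                      cluster_p = numeric())
  if (!any(sel)) return(empty)
  lab <- label_components(sel, connectivity)
  vv <- voxel_volume_mm3(tmap$grid)
  keep <- which(lab$sizes * vv >= extent_mm3)
  if (!length(keep)) return(empty)
  rows <- lapply(keep, function(k) {
    vox <- which(lab$labels == k)
    stat <- if (two_sided) abs(tmap$values[vox]) else tmap$values[vox]
    pk <- vox[which.max(stat)]
    ijk <- arrayInd(pk, tmap$grid$shape)
    data.frame(size_voxels = length(vox), size_mm3 = length(vox) * vv,
               peak_stat = tmap$values[pk],
               peak_x_mm = axis_coords(tmap$grid, 1)[ijk[1]],
               peak_y_mm = axis_coords(tmap$grid, 2)[ijk[2]],
               peak_z_mm = axis_coords(tmap$grid, 3)[ijk[3]],
               cluster_p = NA_real_)
  })
  out <- do.call(rbind, rows)
  out[order(out$size_voxels, decreasing = TRUE), , drop = FALSE]
}

#' Permutation-based cluster-level correction
#'
#' Attaches family-wise-corrected cluster p-values to the suprathreshold
#' clusters of a voxel-wise GLM by permutation under the Freedman-Lane
#' scheme: the outcome images are reduced to residuals of the nuisance-only
#' model (the design columns with zero contrast weight), the residuals are
#' row-permuted and added back to the nuisance fit, and the full model is
#' refitted to each permuted dataset. The null statistic is the maximum
#' suprathreshold cluster size, so
#' `cluster_p = (1 + #{max cluster size in permutation >= observed size}) / (1 + n_perm)`,
#' which controls the family-wise error over the whole volume.
#'
#' @inheritParams fit_voxelwise_glm
#' @param n_perm Number of permutations, >= 100.
#' @param seed Integer seed for the permutation stream.
#' @param voxel_p,extent_mm3,connectivity,two_sided As in
#'   [extract_clusters()].
#' @return The observed cluster table (see [extract_clusters()]) with
#'   `cluster_p` filled in; the permutation null of maximum cluster sizes is
#'   attached as `attr(, "perm_max_sizes")` and the observed t map as
#'   `attr(, "tmap")`.
#' @export
permutation_cluster_p <- function(images, design, contrast, n_perm = 1000,
                                  seed = 1, voxel_p = 0.001, extent_mm3 = 800,
                                  connectivity = 26, two_sided = FALSE) {
  if (n_perm < 100) stop("'n_perm' must be >= 100 for usable cluster p-values")
  grid <- assert_same_grid(images)
  design <- as.matrix(design)
  if (length(contrast) != ncol(design))
    stop("contrast length must equal the number of design columns")
  if (all(contrast == 0)) stop("contrast must not be all zeros")
  Y <- do.call(rbind, lapply(images, function(v) as.vector(v$values)))
  obs <- glm_t_values(Y, design, contrast)
  tmap <- scalar_volume(array(obs$t, grid$shape), grid)
  attr(tmap, "df") <- obs$df
  clusters <- extract_clusters(tmap, obs$df, voxel_p, extent_mm3,
                               connectivity, two_sided)
  t_crit <- stats::qt(1 - voxel_p, obs$df)
  # Freedman-Lane: permute residuals of the nuisance-only model
  Z <- design[, contrast == 0, drop = FALSE]
  if (ncol(Z) == 0L) Z <- matrix(1, nrow(design), 1L)
  Hz <- Z %*% chol2inv(chol(crossprod(Z))) %*% t(Z)
  Fit <- Hz %*% Y
  Res <- Y - Fit
  n <- nrow(Y)
  set.seed(as.integer(seed))
  max_sizes <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    Yp <- Fit + Res[sample.int(n), , drop = FALSE]
    tp <- glm_t_values(Yp, design, contrast)$t
    sel <- if (two_sided) abs(tp) >= t_crit else tp >= t_crit
    max_sizes[b] <- if (any(sel)) {
      max(label_components(array(sel, grid$shape), connectivity)$sizes)
    } else 0L
  }
  if (nrow(clusters)) {
    clusters$cluster_p <- vapply(clusters$size_voxels, function(s)
      (1 + sum(max_sizes >= s)) / (1 + n_perm), 0)
  }
  attr(clusters, "perm_max_sizes") <- max_sizes
  attr(clusters, "tmap") <- tmap
  clusters
}
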