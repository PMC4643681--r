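#' Crawford-Howell single-case t statistic
#'
#' Compares one observation against a small control sample:
#' \deqn{t = \frac{x - \bar{c}}{s_c \sqrt{(n+1)/n}}, \quad df = n - 1,}
#' where \eqn{\bar{c}} and \eqn{s_c} are the control mean and sample
#' standard deviation (n-1 denominator) and n the number of controls. The
#' inflation factor \eqn{\sqrt{(n+1)/n}} accounts for the control mean being
#' itself an estimate, so the test remains calibrated for small control
#' samples. Applied voxel-wise, it turns a patient image plus a control
#' reference into an outlier t-score map.
#'
#' @param x Observed value(s); vectorised.
#' @param mean Control mean(s), recycled against `x`.
#' @param sd Control sample standard deviation(s), all > 0.
#' @param n Number of controls, >= 2.
#' @return A list with `t` (numeric, same length as the broadcast inputs)
#'   and `df` (= n - 1).
#' @examples
#' crawford_howell_t(102.83, 100, 2.83, 20)
#' @export
crawford_howell_t <- function(x, mean, sd, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("'n' must be a single integer >= 2")
  if (any(sd <= 0)) stop("'sd' must be positive (degenerate voxel: sd = 0)")
  list(t = (x - mean) / (sd * sqrt((n + 1) / n)), df = as.integer(n) - 1L)
}

#' Build a control reference from control volumes
#'
#' Voxel-wise sample mean and sample standard deviation (n-1 denominator)
#' over a set of control images on a common grid; this is the "normal range"
#' against which each patient voxel is tested.
#'
#' @param controls A list of at least two [scalar_volume]s sharing one grid.
#' @return A `control_reference`: list with `mean` and `sd` (3-D arrays),
#'   `n`, and `grid`.
#' @export
fit_control_reference <- function(controls) {
  if (!is.list(controls) || length(controls) < 2L)
    stop("need at least 2 control volumes")
  grid <- assert_same_grid(controls)
  n <- length(controls)
  m <- array(0, grid$shape)
  for (v in controls) m <- m + v$values
  m <- m / n
  ss <- array(0, grid$shape)
  for (v in controls) ss <- ss + (v$values - m)^2
  s <- sqrt(ss / (n - 1))
  structure(list(mean = m, sd = s, n = as.integer(n), grid = grid),
            class = "control_reference")
}

#' @export
print.control_reference <- function(x, ...) {
  cat(sprintf("<control_reference> n = %d controls, mean sd = %.3f, on ",
              x$n, mean(x$sd)))
  print(x$grid)
  invisible(x)
}

#' Voxel-wise Crawford-Howell outlier map
#'
#' Computes the Crawford-Howell t statistic at every voxel of a patient
#' image against a [fit_control_reference()] reference, producing a map
#' coding each voxel's degree of abnormality. Hypointense (lesioned) tissue
#' yields negative t. Voxels whose control sd falls below a floor of
#' `1e-6 * mean(sd)` are degenerate (the statistic is undefined); they are
#' set to t = 0 and counted in the `degenerate_voxels` attribute.
#'
#' @param patient A [scalar_volume] on the reference grid.
#' @param ref A `control_reference`.
#' @return A [scalar_volume] of t values with attributes `df` and
#'   `degenerate_voxels`.
#' @export
t_map <- function(patient, ref) {
  stopifnot(inherits(patient, "scalar_volume"), inherits(ref, "control_reference"))
  assert_same_grid(list(patient = patient, controls = ref$grid))
  floor_sd <- 1e-6 * mean(ref$sd)
  degen <- ref$sd <= floor_sd
  s <- ifelse(degen, 1, ref$sd)
  tv <- (patient$values - ref$mean) / (s * sqrt((ref$n + 1) / ref$n))
  tv[degen] <- 0
  out <- scalar_volume(tv, ref$grid)
  attr(out, "df") <- ref$n - 1L
  attr(out, "degenerate_voxels") <- sum(degen)
  out
}

#' Threshold a t-score map into a binary lesion map
#'
#' For the default hypointense tail (ischemic damage on CT is darker than
#' normal tissue) the lesion mask is the set of voxels with t <= -t_threshold;
#' `"hyperintense"` takes t >= t_threshold and `"two_sided"` takes |t| >=
#' t_threshold. Optionally, connected components (26-connectivity) smaller
#' than `min_cluster_voxels` are removed, which suppresses isolated
#' noise-driven detections.
#'
#' @param tmap A [scalar_volume] of t values (see [t_map()]).
#' @param t_threshold Positive threshold on |t|.
#' @param tail `"hypointense"` (default), `"hyperintense"` or `"two_sided"`.
#' @param min_cluster_voxels Minimum connected-component size kept; 0 (the
#'   default) disables the cleanup.
#' @return A [mask_volume].
#' @export
binarize_lesion <- function(tmap, t_threshold, tail = c("hypointense", "hyperintense", "two_sided"),
                            min_cluster_voxels = 0L) {
  stopifnot(inherits(tmap, "scalar_volume"))
  tail <- match.arg(tail)
  if (!is.numeric(t_threshold) || length(t_threshold) != 1L || t_threshold <= 0)
    stop("'t_threshold' must be a single positive number")
  sel <- switch(tail,
                hypointense  = tmap$values <= -t_threshold,
                hyperintense = tmap$values >= t_threshold,
                two_sided    = abs(tmap$values) >= t_threshold)
  if (min_cluster_voxels > 0L && any(sel)) {
    lab <- label_components(sel, connectivity = 26)
    keep <- which(lab$sizes >= min_cluster_voxels)
    sel <- array(lab$labels %in% keep & lab$labels > 0L, dim = dim(sel))
  }
  mask_volume(sel, tmap$grid)
}

#' Default lesion-map threshold
#'
#' The t value whose one-tailed tail probability is `p` at `n - 1` degrees of
#' freedom. The delineation literature does not fix a universal cut-off; the
#' package default is one-tailed p = 0.01, explicit and configurable.
#'
#' @param n Number of controls.
#' @param p One-tailed tail probability, default 0.01.
#' @return Positive t threshold.
#' @export
auto_t_threshold <- function(n, p = 0.01) {
  if (n < 2) stop("'n' must be >= 2")
  if (p <= 0 || p >= 1) stop("'p' must be in (0,1)")
  stats::qt(1 - p, df = n - 1)
}

#' Automated lesion delineation for one patient
#'
#' Composition of [t_map()], [binarize_lesion()] and [volume_cc()]: the
#' patient image is converted to a Crawford-Howell outlier map against the
#' control reference, thresholded into a binary lesion map, and the lesion
#' volume is measured.
#'
#' @param patient A [scalar_volume].
#' @param ref A `control_reference` from [fit_control_reference()].
#' @param t_threshold Threshold on |t|; `NULL` (default) uses
#'   [auto_t_threshold()] at one-tailed p = 0.01.
#' @param tail,min_cluster_voxels Passed to [binarize_lesion()].
#' @return A list with `mask` ([mask_volume]), `lesion_volume_cc`, and
#'   `report` (threshold used, df, degenerate voxel count).
#' @export
delineate <- function(patient, ref, t_threshold = NULL,
                      tail = "hypointense", min_cluster_voxels = 0L) {
  if (is.null(t_threshold)) t_threshold <- auto_t_threshold(ref$n)
  tm <- t_map(patient, ref)
  mask <- binarize_lesion(tm, t_threshold, tail, min_cluster_voxels)
  list(mask = mask,
       lesion_volume_cc = volume_cc(mask),
       report = list(t_threshold = t_threshold,
                     df = attr(tm, "df"),
                     tail = tail,
                     min_cluster_voxels = as.integer(min_cluster_voxels),
                     degenerate_voxels = attr(tm, "degenerate_voxels"),
                     lesion_voxels = sum(mask$values)))
}

#' Dice overlap coefficient between two masks
#'
#' 2|A n B| / (|A| + |B|); 1 for identical nonempty masks, 0 for disjoint.
#' Conventionally 1 when both masks are empty. Used to validate recovered
#' lesion masks against simulated ground truth.
#'
#' @param a,b [mask_volume]s on one grid.
#' @return Scalar in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  assert_same_grid(list(a, b))
  na <- sum(a$values); nb <- sum(b$values)
  if (na + nb == 0L) return(1)
  2 * sum(a$values & b$values) / (na + nb)
}
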