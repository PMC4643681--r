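#' Define a regular 3-D voxel grid
#'
#' A `volume_grid` fixes the sampling of every image in an analysis: the
#' number of voxels per axis, the voxel spacing in millimetres, and the world
#' coordinate (RAS-oriented: +x right, +y anterior, +z superior) of the
#' centre of voxel `(1,1,1)`. All volumes entering a joint analysis must
#' share one grid; no resampling is performed anywhere in the package.
#'
#' @param shape Integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing_mm Numeric vector of length 3, voxel spacing in mm (all > 0).
#'   A scalar is recycled to all three axes.
#' @param origin_mm Numeric vector of length 3, world coordinate in mm of the
#'   first voxel's centre. Defaults to centring the grid on the world origin,
#'   which places the interhemispheric midline at x = 0.
#' @return An object of class `volume_grid`.
#' @examples
#' g <- volume_grid(c(32, 36, 32), 2)
#' voxel_volume_mm3(g)  # 8
#' @export
volume_grid <- function(shape, spacing_mm = 2, origin_mm = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be 3 integers, all >= 1")
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("'spacing_mm' must be 3 positive numbers")
  if (is.null(origin_mm)) origin_mm <- -(shape - 1L) * spacing_mm / 2
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("'origin_mm' must be 3 finite numbers")
  structure(list(shape = shape, spacing_mm = spacing_mm, origin_mm = origin_mm),
            class = "volume_grid")
}

#' @rdname volume_grid
#' @param grid A `volume_grid`.
#' @export
voxel_volume_mm3 <- function(grid) {
  stopifnot(inherits(grid, "volume_grid"))
  prod(grid$spacing_mm)
}

#' World coordinates of all voxel centres along one axis
#' @noRd
axis_coords <- function(grid, axis) {
  grid$origin_mm[axis] + (seq_len(grid$shape[axis]) - 1L) * grid$spacing_mm[axis]
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing %s mm, origin (%s) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(format(x$spacing_mm), collapse = " x "),
              paste(format(x$origin_mm), collapse = ", ")))
  invisible(x)
}

#' Scalar and mask volumes
#'
#' `scalar_volume()` wraps a numeric 3-D array (an image, a t-score map, a
#' tract probability map) on a [volume_grid]; all values must be finite.
#' `mask_volume()` wraps a logical array (a binary lesion map, a thresholded
#' tract, a hemisphere mask).
#'
#' @param values A 3-D array congruent with `grid$shape` (numeric for
#'   `scalar_volume`, logical or 0/1 for `mask_volume`).
#' @param grid A [volume_grid].
#' @return An object of class `scalar_volume` or `mask_volume` (both also
#'   class `volume`), a list with fields `values` and `grid`.
#' @export
scalar_volume <- function(values, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  values <- as.array(values)
  if (!identical(dim(values), NULL) && length(dim(values)) != 3L)
    stop("'values' must be a 3-D array")
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("'values' dimensions do not match grid shape")
  storage.mode(values) <- "double"
  if (any(!is.finite(values)))
    stop("scalar volume contains non-finite values (NaN/Inf/NA)")
  structure(list(values = values, grid = grid), class = c("scalar_volume", "volume"))
}

#' @rdname scalar_volume
#' @export
mask_volume <- function(values, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3-D array")
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("'values' dimensions do not match grid shape")
  if (is.numeric(values)) {
    if (any(is.na(values)) || !all(values %in% c(0, 1)))
      stop("numeric mask values must all be 0 or 1")
    values <- array(values != 0, dim = dim(values))
  }
  if (!is.logical(values)) stop("'values' must be logical or 0/1 numeric")
  if (any(is.na(values))) stop("mask contains NA")
  structure(list(values = values, grid = grid), class = c("mask_volume", "volume"))
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume> range [%g, %g] on ", min(x$values), max(x$values)))
  print(x$grid)
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("<mask_volume> %d true voxels (%.3f cc) on ",
              sum(x$values), volume_cc(x)))
  print(x$grid)
  invisible(x)
}

#' Check that volumes share a common grid
#'
#' Every joint operation in the package (control references, overlap volumes,
#' group maps, voxel-wise GLMs) assumes all inputs live on one grid. This
#' verifies shape exactly, spacing to 1e-6 mm and origin to 1e-3 mm (the
#' tolerances absorb float32 NIfTI header round-trips), and fails naming the
#' first offending volume.
#'
#' @param vols A list of `volume` and/or `volume_grid` objects (or a single
#'   such object, against which nothing is compared).
#' @return Invisibly, the common `volume_grid`.
#' @export
assert_same_grid <- function(vols) {
  if (inherits(vols, "volume") || inherits(vols, "volume_grid")) vols <- list(vols)
  if (!is.list(vols) || length(vols) == 0L)
    stop("'vols' must be a nonempty list of volumes or grids")
  grids <- lapply(vols, function(v) if (inherits(v, "volume_grid")) v else v$grid)
  ref <- grids[[1L]]
  nm <- names(vols)
  for (i in seq_along(grids)[-1L]) {
    g <- grids[[i]]
    lab <- if (!is.null(nm) && nzchar(nm[i])) sprintf("'%s'", nm[i]) else sprintf("element %d", i)
    if (!identical(g$shape, ref$shape))
      stop(sprintf("grid mismatch at %s: shape (%s) vs (%s)", lab,
                   paste(g$shape, collapse = ","), paste(ref$shape, collapse = ",")))
    if (any(abs(g$spacing_mm - ref$spacing_mm) > 1e-6))
      stop(sprintf("grid mismatch at %s: spacing differs by more than 1e-6 mm", lab))
    if (any(abs(g$origin_mm - ref$origin_mm) > 1e-3))
      stop(sprintf("grid mismatch at %s: origin differs by more than 1e-3 mm", lab))
  }
  invisible(ref)
}

#' Volume of a binary mask in cubic centimetres
#'
#' The disconnection measure and all lesion volumes are expressed in cm^3:
#' number of true voxels times the voxel volume in mm^3, divided by 1000.
#'
#' @param mask A [mask_volume].
#' @return Nonnegative scalar, cm^3.
#' @examples
#' g <- volume_grid(c(10, 10, 10), 2)
#' m <- array(FALSE, c(10, 10, 10)); m[1:4, 1:5, 1:5] <- TRUE
#' volume_cc(mask_volume(m, g))  # 100 voxels x 8 mm^3 / 1000 = 0.8
#' @export
volume_cc <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  sum(mask$values) * voxel_volume_mm3(mask$grid) / 1000
}

#' Read a single 3-D NIfTI-1 volume
#'
#' The header must describe an axis-aligned RAS grid (no rotation or shear);
#' spacing is taken from the transform's diagonal and the origin from its
#' translation column. Multi-volume (4-D) files and files containing
#' non-finite voxels are rejected.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param as_mask If `TRUE`, return a [mask_volume] (file values must all be
#'   0 or 1); otherwise a [scalar_volume].
#' @return A [scalar_volume] or [mask_volume].
#' @export
read_volume <- function(path, as_mask = FALSE) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) { dim(img) <- d[1:3]; d <- d[1:3] }
  if (length(d) != 3L)
    stop(sprintf("'%s' is not a single 3-D volume (dims: %s)", path,
                 paste(d, collapse = "x")))
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  if (any(abs(rot - diag(diag(rot))) > 1e-4 * max(abs(diag(rot)))))
    stop(sprintf("'%s': oblique or rotated orientation not supported; resample to an axis-aligned RAS grid first", path))
  spacing <- diag(rot)
  if (any(spacing <= 0))
    stop(sprintf("'%s': transform is not RAS-positive", path))
  grid <- volume_grid(d, spacing, xf[1:3, 4])
  vals <- array(as.numeric(img), dim = d)
  if (any(!is.finite(vals)))
    stop(sprintf("'%s' contains %d non-finite voxel(s)", path, sum(!is.finite(vals))))
  if (as_mask) {
    if (!all(vals %in% c(0, 1)))
      stop(sprintf("'%s': mask file contains values other than 0/1", path))
    mask_volume(vals != 0, grid)
  } else {
    scalar_volume(vals, grid)
  }
}

#' Write a volume as NIfTI-1
#'
#' Scalar volumes are stored as float32, masks as uint8 0/1. The grid's
#' spacing and origin are encoded in the sform (code 2, aligned).
#'
#' @param vol A [scalar_volume] or [mask_volume].
#' @param path Output path ending in `.nii` or `.nii.gz`; the parent
#'   directory must exist.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume"))
  if (!dir.exists(dirname(path)))
    stop(sprintf("directory does not exist: '%s'", dirname(path)))
  is_mask <- inherits(vol, "mask_volume")
  vals <- if (is_mask) array(as.integer(vol$values), dim = vol$grid$shape) else vol$values
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- vol$grid$spacing_mm
  xf <- diag(c(vol$grid$spacing_mm, 1))
  xf[1:3, 4] <- vol$grid$origin_mm
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path, datatype = if (is_mask) "uint8" else "float")
  invisible(path)
}

#' Gaussian smoothing of a scalar volume
#'
#' Separable per-axis Gaussian with sigma = FWHM / (2 sqrt(2 ln 2)) converted
#' to voxel units by each axis's spacing, truncated at 4 sigma and
#' renormalised so a constant volume is exactly preserved. Boundaries are
#' handled by symmetric reflection, which conserves the voxel sum for mass
#' away from the edges.
#'
#' @param vol A [scalar_volume].
#' @param fwhm_mm Full width at half maximum in mm, > 0.
#' @return A [scalar_volume] on the same grid.
#' @export
gaussian_smooth <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "scalar_volume"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || !is.finite(fwhm_mm) || fwhm_mm <= 0)
    stop("'fwhm_mm' must be a single positive number")
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vol$grid$spacing_mm
  out <- vol$values
  for (axis in 1:3) out <- smooth_axis(out, sigma_vox[axis], axis)
  scalar_volume(out, vol$grid)
}

# 1-D Gaussian convolution along one array axis, symmetric reflection at the
# edges (index i maps to 1-i below, 2n+1-i above).
#' @noRd
smooth_axis <- function(arr, sigma_vox, axis) {
  if (sigma_vox < 1e-8) return(arr)
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  k <- stats::dnorm(-r:r, sd = sigma_vox)
  k <- k / sum(k)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- dim(a)[1L]
  out <- array(0, dim(a))
  for (o in -r:r) {
    idx <- seq_len(n) + o
    idx <- ifelse(idx < 1L, 1L - idx, idx)
    idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
    # deep reflection can re-exit the range on tiny axes; fold until inside
    while (any(idx < 1L | idx > n)) {
      idx <- ifelse(idx < 1L, 1L - idx, idx)
      idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
    }
    out <- out + k[o + r + 1L] * a[idx, , , drop = FALSE]
  }
  aperm(out, order(perm))
}

#' Hemisphere masks from the world x-coordinate
#'
#' Left is world x < 0, right is x > 0 (RAS convention, as in MNI space).
#' Voxels whose centre lies within half a voxel of the midplane (|x| <
#' spacing/2) belong to neither mask, so the two hemispheres are always
#' disjoint and never double-count midline structures.
#'
#' @param grid A [volume_grid].
#' @param side `"left"` or `"right"`.
#' @return A [mask_volume].
#' @export
hemisphere_mask <- function(grid, side = c("left", "right")) {
  side <- match.arg(side)
  x <- axis_coords(grid, 1L)
  half <- grid$spacing_mm[1L] / 2
  sel <- if (side == "left") x <= -half else x >= half
  m <- array(FALSE, grid$shape)
  m[sel, , ] <- TRUE
  mask_volume(m, grid)
}

#' Connected components of a 3-D mask
#'
#' Labels the true voxels of a mask by face/edge/corner adjacency. Used for
#' minimum-cluster cleanup of lesion maps and for cluster-extent thresholding
#' of statistical maps.
#'
#' @param mask A [mask_volume] or a logical 3-D array.
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (full neighbourhood).
#' @return A list with `labels` (integer array, 0 = background, components
#'   numbered from 1 in decreasing size order) and `sizes` (integer vector of
#'   component voxel counts).
#' @export
label_components <- function(mask, connectivity = 26) {
  arr <- if (inherits(mask, "mask_volume")) mask$values else mask
  stopifnot(is.logical(arr), length(dim(arr)) == 3L)
  if (!connectivity %in% c(6, 18, 26)) stop("'connectivity' must be 6, 18 or 26")
  d <- dim(arr)
  vox <- which(arr)
  labels <- array(0L, d)
  if (length(vox) == 0L) return(list(labels = labels, sizes = integer(0)))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(offs))
  offs <- offs[ord > 0 & ord <= switch(as.character(connectivity),
                                       "6" = 1, "18" = 2, "26" = 3), , drop = FALSE]
  # half-space of offsets: each undirected adjacency found once
  keep <- offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 | (offs[, 2] == 0 & offs[, 1] > 0)))
  offs <- offs[keep, , drop = FALSE]
  id <- array(0L, d)
  id[vox] <- seq_along(vox)
  co <- arrayInd(vox, d)
  edges <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    nb <- cbind(co[, 1] + offs[r, 1], co[, 2] + offs[r, 2], co[, 3] + offs[r, 3])
    ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] & nb[, 2] >= 1L & nb[, 2] <= d[2] &
          nb[, 3] >= 1L & nb[, 3] <= d[3]
    lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
    nbid <- id[lin]
    hit <- nbid > 0L
    if (any(hit)) edges[[r]] <- cbind(which(ok)[hit], nbid[hit])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L)
    g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  sizes <- tabulate(memb)
  ord2 <- order(sizes, decreasing = TRUE)
  relabel <- integer(length(sizes))
  relabel[ord2] <- seq_along(sizes)
  labels[vox] <- relabel[memb]
  list(labels = labels, sizes = sizes[ord2])
}
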