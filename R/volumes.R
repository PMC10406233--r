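#' Gridded image containers
#'
#' Light containers for image data on a regular voxel grid. A grid couples an
#' array to its voxel sizes (mm), the world coordinate of the first voxel
#' centre (mm), and an orientation code: a three-letter string (one letter per
#' array axis) saying which anatomical direction each axis points towards,
#' e.g. `"RAS"` = axis 1 runs left-to-Right, axis 2 posterior-to-Anterior,
#' axis 3 inferior-to-Superior. All world-coordinate computations in the
#' package assume data have been brought to `"RAS"` (readers do this on load
#' by default).
#'
#' @param values numeric 4D array (x, y, z, t) of signal values.
#' @param voxel_mm length-3 positive numeric, voxel edge lengths in mm.
#' @param origin_mm length-3 numeric, world coordinate (mm) of the centre of
#'   voxel `[1, 1, 1]`.
#' @param orientation three-letter orientation code (see Details).
#' @return An object of class `vol4d`, `vol3d`, `brain_mask` or
#'   `parcellation`.
#' @name volume-containers
NULL

ORIENT_AXES <- c(R = 1L, L = 1L, A = 2L, P = 2L, S = 3L, I = 3L)
ORIENT_SIGN <- c(R = 1, L = -1, A = 1, P = -1, S = 1, I = -1)

check_orientation <- function(code) {
  letters3 <- strsplit(code, "")[[1]]
  if (length(letters3) != 3L || !all(letters3 %in% names(ORIENT_AXES)) ||
      anyDuplicated(ORIENT_AXES[letters3])) {
    stop("orientation must be a signed permutation of the L-R, P-A, I-S axes, e.g. \"RAS\"",
         call. = FALSE)
  }
  invisible(code)
}

new_grid_obj <- function(values, voxel_mm, origin_mm, orientation, class) {
  stopifnot(is.array(values))
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) != 3L || any(!is.finite(voxel_mm)) || any(voxel_mm <= 0)) {
    stop("voxel_mm must be 3 positive finite numbers", call. = FALSE)
  }
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm))) {
    stop("origin_mm must be 3 finite numbers", call. = FALSE)
  }
  check_orientation(orientation)
  structure(
    list(values = values, voxel_mm = voxel_mm, origin_mm = origin_mm,
         orientation = orientation),
    class = class
  )
}

#' @rdname volume-containers
#' @export
vol4d <- function(values, voxel_mm = c(3, 3, 3), origin_mm = c(0, 0, 0),
                  orientation = "RAS") {
  if (length(dim(values)) != 4L) {
    stop("vol4d requires a 4-dimensional array (x, y, z, t); got ",
         length(dim(values)), " dimensions", call. = FALSE)
  }
  if (dim(values)[4] < 1L) stop("vol4d needs at least one time point", call. = FALSE)
  new_grid_obj(values, voxel_mm, origin_mm, orientation, "vol4d")
}

#' @rdname volume-containers
#' @export
vol3d <- function(values, voxel_mm = c(3, 3, 3), origin_mm = c(0, 0, 0),
                  orientation = "RAS") {
  if (length(dim(values)) != 3L) {
    stop("vol3d requires a 3-dimensional array", call. = FALSE)
  }
  new_grid_obj(values, voxel_mm, origin_mm, orientation, "vol3d")
}

#' @rdname volume-containers
#' @param member logical 3D array, TRUE for in-mask voxels.
#' @export
brain_mask <- function(member, voxel_mm = c(3, 3, 3), origin_mm = c(0, 0, 0),
                       orientation = "RAS") {
  if (length(dim(member)) != 3L) stop("mask must be a 3D array", call. = FALSE)
  storage.mode(member) <- "logical"
  new_grid_obj(member, voxel_mm, origin_mm, orientation, "brain_mask")
}

#' @rdname volume-containers
#' @param labels nonnegative-integer 3D array, 0 = background.
#' @export
parcellation <- function(labels, voxel_mm = c(3, 3, 3), origin_mm = c(0, 0, 0),
                         orientation = "RAS") {
  if (length(dim(labels)) != 3L) stop("parcellation must be a 3D array", call. = FALSE)
  if (any(labels < 0) || any(labels != round(labels))) {
    stop("parcellation labels must be nonnegative integers", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  obj <- new_grid_obj(labels, voxel_mm, origin_mm, orientation, "parcellation")
  obj$region_ids <- sort(unique(labels[labels > 0L]))
  if (length(obj$region_ids) == 0L) stop("parcellation has no nonzero labels", call. = FALSE)
  obj
}

#' @export
print.vol4d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<vol4d> %d x %d x %d voxels x %d time points, voxel %s mm, %s\n",
              d[1], d[2], d[3], d[4],
              paste(format(x$voxel_mm, trim = TRUE), collapse = "x"),
              x$orientation))
  invisible(x)
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %s voxels, %d in mask\n",
              paste(dim(x$values), collapse = "x"), sum(x$values)))
  invisible(x)
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %s voxels, %d regions\n",
              paste(dim(x$values), collapse = "x"), length(x$region_ids)))
  invisible(x)
}

n_timepoints <- function(vol) dim(vol$values)[4]

spatial_dims <- function(x) dim(x$values)[1:3]

#' Check that two gridded objects share a grid
#'
#' Compares spatial dimensions, voxel sizes, origin and orientation.
#' @param a,b gridded objects.
#' @param tol numeric tolerance for voxel size / origin comparison (mm).
#' @return TRUE invisibly; errors otherwise.
#' @export
check_same_grid <- function(a, b, tol = 1e-4) {
  ok <- identical(spatial_dims(a), spatial_dims(b)) &&
    max(abs(a$voxel_mm - b$voxel_mm)) < tol &&
    max(abs(a$origin_mm - b$origin_mm)) < tol &&
    identical(a$orientation, b$orientation)
  if (!ok) stop("objects are not on the same voxel grid", call. = FALSE)
  invisible(TRUE)
}

#' World coordinates of voxel centres
#'
#' Converts 1-based array indices to world coordinates (mm) under the object's
#' orientation code: along array axis i the coordinate on anatomical axis
#' `axis(i)` is `origin + sign * (index - 1) * voxel`.
#'
#' @param x a gridded object.
#' @param idx integer matrix with 3 columns of 1-based voxel indices; by
#'   default all voxels of the grid.
#' @return numeric matrix with columns `x_mm`, `y_mm`, `z_mm` (world L-R,
#'   P-A, I-S axes).
#' @export
voxel_coords_mm <- function(x, idx = NULL) {
  d <- spatial_dims(x)
  if (is.null(idx)) {
    idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                                 k = seq_len(d[3]), KEEP.OUT.ATTRS = FALSE))
  }
  letters3 <- strsplit(x$orientation, "")[[1]]
  out <- matrix(NA_real_, nrow(idx), 3L,
                dimnames = list(NULL, c("x_mm", "y_mm", "z_mm")))
  for (i in 1:3) {
    world_axis <- ORIENT_AXES[[letters3[i]]]
    out[, world_axis] <- x$origin_mm[world_axis] +
      ORIENT_SIGN[[letters3[i]]] * (idx[, i] - 1) * x$voxel_mm[i]
  }
  out
}

#' Flip a gridded object along one array axis
#'
#' Reverses the data along `axis` and updates the orientation code and origin
#' so that world coordinates of voxels are preserved.
#'
#' @param x a gridded object.
#' @param axis array axis to flip (1, 2 or 3).
#' @return The flipped object.
#' @export
flip_axis <- function(x, axis) {
  stopifnot(axis %in% 1:3)
  d <- dim(x$values)
  idx <- rep(list(quote(expr = )), length(d))
  idx[[axis]] <- rev(seq_len(d[axis]))
  x$values <- do.call(`[`, c(list(x$values), idx, list(drop = FALSE)))
  letters3 <- strsplit(x$orientation, "")[[1]]
  opposite <- c(R = "L", L = "R", A = "P", P = "A", S = "I", I = "S")
  world_axis <- ORIENT_AXES[[letters3[axis]]]
  # world coordinate of the (new) first voxel
  x$origin_mm[world_axis] <- x$origin_mm[world_axis] +
    ORIENT_SIGN[[letters3[axis]]] * (d[axis] - 1) * x$voxel_mm[axis]
  letters3[axis] <- opposite[[letters3[axis]]]
  x$orientation <- paste(letters3, collapse = "")
  x
}

#' Extract in-mask voxel time series as a matrix
#'
#' @param vol a [vol4d] object.
#' @param mask a [brain_mask] on the same grid.
#' @return numeric matrix, time points x in-mask voxels, voxels in array
#'   (column-major) order.
#' @export
vol_matrix <- function(vol, mask) {
  check_same_grid(vol, mask)
  d <- dim(vol$values)
  flat <- matrix(vol$values, prod(d[1:3]), d[4])
  t(flat[as.vector(mask$values), , drop = FALSE])
}

#' Mean time series over each parcellation region
#'
#' Averages the 4D signal over the member voxels of every region.
#'
#' @param vol a [vol4d] object.
#' @param parc a [parcellation] on the same grid.
#' @return numeric matrix, time points x regions, columns named by region id.
#' @export
roi_series <- function(vol, parc) {
  check_same_grid(vol, parc)
  d <- dim(vol$values)
  flat <- matrix(vol$values, prod(d[1:3]), d[4])
  lab <- as.vector(parc$values)
  out <- vapply(parc$region_ids, function(r) {
    colMeans(flat[lab == r, , drop = FALSE])
  }, numeric(d[4]))
  colnames(out) <- as.character(parc$region_ids)
  out
}

#' Region centroids in world coordinates
#'
#' @param parc a [parcellation].
#' @return tibble with columns `region`, `n_voxels`, `x_mm`, `y_mm`, `z_mm`;
#'   centroids are means of member-voxel world coordinates.
#' @export
region_centroids <- function(parc) {
  idx <- which(parc$values > 0L, arr.ind = TRUE)
  xyz <- voxel_coords_mm(parc, idx)
  lab <- parc$values[parc$values > 0L]
  agg <- rowsum(cbind(1, xyz), group = lab)
  tibble::tibble(
    region = as.integer(rownames(agg)),
    n_voxels = as.integer(agg[, 1]),
    x_mm = agg[, 2] / agg[, 1],
    y_mm = agg[, 3] / agg[, 1],
    z_mm = agg[, 4] / agg[, 1]
  )
}
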