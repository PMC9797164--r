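# Core geometric data model: scalar volumes, binary masks and paired point
# sets, all living in a common world coordinate frame (mm).
#
# Conventions (fixed for the whole package):
#   * world coordinates are in mm; voxel indices are 0-based;
#   * world(v) = origin + v * spacing, component-wise, identity direction
#     matrix (oblique scans are out of scope);
#   * transforms map FIXED-image world coordinates to MOVING-image world
#     coordinates (backward mapping).

#' Create a 3D scalar volume with physical geometry
#'
#' A volume is a 3D array of intensities (CT-like, arbitrary units) plus the
#' physical geometry needed to place voxels in world space: a per-axis
#' spacing (mm/voxel) and the world position of voxel `(0,0,0)`.
#'
#' @param data 3D numeric array of intensities; must be finite everywhere.
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin numeric length-3, world coordinates (mm) of the first voxel
#'   center.
#' @return An object of class `mmdir_volume`.
#' @examples
#' v <- volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 2.5))
#' voxel_to_world(v, c(1, 1, 1))
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array")
  storage.mode(data) <- "double"
  if (anyNA(data) || any(!is.finite(data)))
    stop("volume data contains non-finite values")
  spacing <- as.double(spacing); origin <- as.double(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite values")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "mmdir_volume")
}

#' @export
print.mmdir_volume <- function(x, ...) {
  cat(sprintf("<mmdir_volume> %s voxels, spacing (%s) mm, origin (%s) mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Create a binary label mask on a volume grid
#'
#' A mask shares the grid geometry of its parent volume exactly; values are
#' strictly binary. Geometry mismatches are always rejected at construction,
#' never silently resampled.
#'
#' @param data 3D logical or 0/1 numeric array.
#' @param like optional `mmdir_volume` or `mmdir_mask` supplying geometry.
#' @param spacing,origin geometry, used when `like` is not given.
#' @return An object of class `mmdir_mask`.
#' @export
label_mask <- function(data, like = NULL, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)) {
  if (!is.null(like)) {
    spacing <- like$spacing; origin <- like$origin
    if (!identical(dim(data), dim(like$data)))
      stop("mask dimensions do not match the reference grid")
  }
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask data must be a 3D array")
  if (is.logical(data)) {
    if (anyNA(data)) stop("mask data contains NA")
    m <- data
  } else {
    if (anyNA(data) || !all(data %in% c(0, 1)))
      stop("mask values must be 0 or 1")
    m <- array(data != 0, dim(data))
  }
  spacing <- as.double(spacing); origin <- as.double(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three strictly positive values")
  structure(list(data = m, spacing = spacing, origin = as.double(origin)),
            class = "mmdir_mask")
}

#' @export
print.mmdir_mask <- function(x, ...) {
  cat(sprintf("<mmdir_mask> %s voxels, %d foreground, spacing (%s) mm\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              paste(format(x$spacing), collapse = ", ")))
  invisible(x)
}

#' Check that two volumes/masks live on the same grid
#' @param a,b volumes or masks.
#' @param tol tolerance on spacing/origin (mm).
#' @return logical scalar.
#' @export
same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

.stop_geometry <- function(what = "inputs") {
  stop(sprintf("%s must share the same grid geometry", what))
}

.as_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  p <- as.matrix(p)
  if (ncol(p) != 3L) stop("points must be an N x 3 matrix")
  storage.mode(p) <- "double"
  dimnames(p) <- NULL
  p
}

#' Convert world coordinates (mm) to continuous 0-based voxel indices
#'
#' Exact inverse of [voxel_to_world()]. Points outside the grid are returned
#' with out-of-range indices; the caller decides how to treat them.
#'
#' @param vol an `mmdir_volume` or `mmdir_mask`.
#' @param p_world N x 3 matrix (or length-3 vector) of world points.
#' @return N x 3 matrix of continuous voxel indices.
#' @export
world_to_voxel <- function(vol, p_world) {
  p <- .as_points(p_world)
  sweep(sweep(p, 2, vol$origin, "-"), 2, vol$spacing, "/")
}

#' Convert 0-based voxel indices to world coordinates (mm)
#' @param vol an `mmdir_volume` or `mmdir_mask`.
#' @param idx N x 3 matrix (or length-3 vector) of (possibly continuous)
#'   voxel indices.
#' @return N x 3 matrix of world points.
#' @export
voxel_to_world <- function(vol, idx) {
  p <- .as_points(idx)
  sweep(sweep(p, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

# World coordinates of all voxel centers (or a 0-based linear-index subset).
.voxel_center_points <- function(vol, linear0 = NULL) {
  d <- dim(vol$data)
  if (is.null(linear0)) linear0 <- seq_len(prod(d)) - 1L
  i <- linear0 %% d[1]
  j <- (linear0 %/% d[1]) %% d[2]
  k <- linear0 %/% (d[1] * d[2])
  voxel_to_world(vol, cbind(i, j, k))
}

# World extent of the voxel-center lattice: list(lo, hi).
.domain_of <- function(vol) {
  list(lo = vol$origin,
       hi = vol$origin + (dim(vol$data) - 1) * vol$spacing)
}

#' Create a paired landmark set
#'
#' Corresponding landmarks in the fixed and moving image, in world mm.
#' Pairing is positional: row `i` of `fixed` corresponds to row `i` of
#' `moving`. Each pair carries a tissue-group label used by the TRE report.
#'
#' @param fixed,moving N x 3 matrices of world points (mm), N >= 1.
#' @param group character vector (length 1 or N) with values among
#'   `"soft_tissue"`, `"rigid"`, `"boundary"`, `"unassigned"`.
#' @return An object of class `mmdir_points`.
#' @export
paired_points <- function(fixed, moving, group = "unassigned") {
  f <- .as_points(fixed); m <- .as_points(moving)
  if (nrow(f) != nrow(m) || nrow(f) < 1L)
    stop("fixed and moving point lists must have equal, positive length")
  allowed <- c("soft_tissue", "rigid", "boundary", "unassigned")
  group <- as.character(group)
  if (length(group) == 1L) group <- rep(group, nrow(f))
  if (length(group) != nrow(f) || !all(group %in% allowed))
    stop("group labels must be soft_tissue, rigid, boundary or unassigned")
  structure(list(fixed = f, moving = m, group = group),
            class = "mmdir_points")
}

#' @export
print.mmdir_points <- function(x, ...) {
  cat(sprintf("<mmdir_points> %d pairs (%s)\n", nrow(x$fixed),
              paste(sprintf("%s: %d", names(table(x$group)),
                            as.integer(table(x$group))), collapse = ", ")))
  invisible(x)
}

#' @export
length.mmdir_points <- function(x) nrow(x$fixed)

# Subset a paired point set.
.points_subset <- function(p, idx) {
  paired_points(p$fixed[idx, , drop = FALSE],
                p$moving[idx, , drop = FALSE], p$group[idx])
}
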