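# Spatial transforms. All transforms map fixed-image world coordinates (mm)
# into moving-image world coordinates (mm). The free-form deformation is a
# cubic B-spline displacement field on a regular control grid; composition
# with the affine stage is additive in moving world space:
#   T(x) = A x + b + D_mu(x)
# with D_mu evaluated at the fixed-domain coordinate x. Displacement is zero
# beyond the control-grid support (out-of-grid coefficients are zero).

#' Create an affine transform
#' @param matrix 3 x 3 linear part (world mm -> world mm); must be
#'   invertible.
#' @param translation length-3 translation (mm).
#' @return An object of class `mmdir_affine`.
#' @export
affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  m <- base::matrix(as.double(matrix), 3, 3)
  t <- as.double(translation)
  if (length(t) != 3L || any(!is.finite(m)) || any(!is.finite(t)))
    stop("affine parameters must be finite")
  if (abs(det(m)) < 1e-12) stop("affine matrix is singular")
  structure(list(matrix = m, translation = t), class = "mmdir_affine")
}

#' Create a cubic B-spline free-form deformation
#'
#' @param grid_origin world position (mm) of control point `(0,0,0)`.
#' @param grid_spacing control-point spacing (mm), length 3 (or 1, recycled).
#' @param grid_dim number of control points per axis, length 3.
#' @param coefficients displacement coefficients, array
#'   `c(grid_dim, 3)` (mm); zero coefficients give the identity mapping.
#' @return An object of class `mmdir_bspline`.
#' @export
bspline_transform <- function(grid_origin, grid_spacing, grid_dim,
                              coefficients = NULL) {
  grid_spacing <- rep(as.double(grid_spacing), length.out = 3)
  grid_dim <- as.integer(grid_dim)
  if (any(grid_spacing <= 0) || length(grid_dim) != 3L || any(grid_dim < 4L))
    stop("control grid needs positive spacing and at least 4 points per axis")
  if (is.null(coefficients))
    coefficients <- array(0, c(grid_dim, 3L))
  if (!identical(dim(coefficients), c(grid_dim, 3L)))
    stop("coefficients must be an array of dim c(grid_dim, 3)")
  storage.mode(coefficients) <- "double"
  if (any(!is.finite(coefficients))) stop("coefficients must be finite")
  structure(list(grid_origin = as.double(grid_origin),
                 grid_spacing = grid_spacing,
                 grid_dim = grid_dim,
                 coefficients = coefficients),
            class = "mmdir_bspline")
}

#' Build a B-spline control grid covering a volume domain
#'
#' The grid covers the voxel-center extent of `vol` plus a two-node margin on
#' every side, so every in-domain point has full cubic support and dyadic
#' refinement is exact over the domain.
#'
#' @param vol an `mmdir_volume` (or mask) defining the domain.
#' @param spacing_mm control-point spacing in mm (length 1 or 3).
#' @return An identity `mmdir_bspline` over the domain.
#' @export
bspline_grid_for <- function(vol, spacing_mm) {
  gs <- rep(as.double(spacing_mm), length.out = 3)
  dom <- .domain_of(vol)
  n <- floor((dom$hi - dom$lo) / gs) + 6L
  bspline_transform(grid_origin = dom$lo - 2 * gs, grid_spacing = gs,
                    grid_dim = as.integer(n))
}

#' Combine an affine stage and a B-spline stage
#'
#' Application order: affine first, then the additive B-spline displacement
#' evaluated at the input (fixed-domain) point. Either part may be `NULL`;
#' with both missing the composite is the identity.
#'
#' @param affine an `mmdir_affine` or `NULL`.
#' @param bspline an `mmdir_bspline` or `NULL`.
#' @return An object of class `mmdir_composite`.
#' @export
composite_transform <- function(affine = NULL, bspline = NULL) {
  if (!is.null(affine) && !inherits(affine, "mmdir_affine"))
    stop("affine part must be an mmdir_affine")
  if (!is.null(bspline) && !inherits(bspline, "mmdir_bspline"))
    stop("bspline part must be an mmdir_bspline")
  structure(list(affine = affine, bspline = bspline),
            class = "mmdir_composite")
}

#' The identity transform
#' @return An identity `mmdir_composite`.
#' @export
identity_transform <- function() composite_transform()

# Displacement of the B-spline field at world points (N x 3).
.bspline_disp <- function(bsp, pts) {
  .cpp_bspline_disp(pts, bsp$grid_origin, bsp$grid_spacing, bsp$grid_dim,
                    as.double(bsp$coefficients))
}

#' Apply a transform to world points
#'
#' Maps points from fixed-image world space to moving-image world space.
#' The identity transform returns its input bit-exactly.
#'
#' @param t an `mmdir_affine`, `mmdir_bspline` or `mmdir_composite`.
#' @param pts N x 3 matrix (or length-3 vector) of world points (mm).
#' @return N x 3 matrix of mapped world points.
#' @export
apply_transform_points <- function(t, pts) {
  pts <- .as_points(pts)
  UseMethod("apply_transform_points")
}

#' @export
apply_transform_points.mmdir_affine <- function(t, pts) {
  pts <- .as_points(pts)
  sweep(pts %*% base::t(t$matrix), 2, t$translation, "+")
}

#' @export
apply_transform_points.mmdir_bspline <- function(t, pts) {
  pts <- .as_points(pts)
  if (all(t$coefficients == 0)) return(pts)
  pts + .bspline_disp(t, pts)
}

#' @export
apply_transform_points.mmdir_composite <- function(t, pts) {
  pts <- .as_points(pts)
  out <- if (is.null(t$affine)) pts else
    apply_transform_points(t$affine, pts)
  if (!is.null(t$bspline) && !all(t$bspline$coefficients == 0))
    out <- out + .bspline_disp(t$bspline, pts)
  out
}

# Extract the B-spline part of a transform (or NULL).
.bspline_part <- function(t) {
  if (inherits(t, "mmdir_bspline")) t
  else if (inherits(t, "mmdir_composite")) t$bspline
  else NULL
}

# Replace the B-spline coefficients inside a (composite) transform.
.with_coefficients <- function(t, coef_vec) {
  b <- .bspline_part(t)
  if (is.null(b)) stop("transform has no B-spline part")
  b$coefficients <- array(as.double(coef_vec), c(b$grid_dim, 3L))
  if (inherits(t, "mmdir_bspline")) return(b)
  t$bspline <- b
  t
}

#' Refine a B-spline grid by dyadic subdivision
#'
#' Halves the control spacing; the represented displacement field is
#' unchanged over the image domain (exact cubic B-spline subdivision with
#' zero padding at the grid edges, absorbed by the two-node margin that
#' [bspline_grid_for()] reserves).
#'
#' @param bsp an `mmdir_bspline`.
#' @return An `mmdir_bspline` with spacing halved and `2n - 1` control
#'   points per axis.
#' @export
refine_bspline <- function(bsp) {
  stopifnot(inherits(bsp, "mmdir_bspline"))
  nd <- bsp$grid_dim
  sub1 <- function(n) {
    # (2n-1) x n dyadic subdivision operator for uniform cubic B-splines
    nf <- 2L * n - 1L
    S <- base::matrix(0, nf, n)
    for (m in seq_len(nf) - 1L) {
      if (m %% 2L == 0L) {  # vertex point m = 2i
        i <- m %/% 2L
        for (d in -1:1) {
          j <- i + d
          if (j >= 0 && j < n) S[m + 1, j + 1] <- c(1, 6, 1)[d + 2] / 8
        }
      } else {              # edge point m = 2i + 1
        i <- (m - 1L) %/% 2L
        for (j in c(i, i + 1L))
          if (j >= 0 && j < n) S[m + 1, j + 1] <- 0.5
      }
    }
    S
  }
  S1 <- sub1(nd[1]); S2 <- sub1(nd[2]); S3 <- sub1(nd[3])
  cf <- bsp$coefficients
  out <- array(0, c(2L * nd - 1L, 3L))
  for (comp in 1:3) {
    a <- cf[, , , comp]
    # axis 1
    a <- array(S1 %*% base::matrix(a, nd[1], nd[2] * nd[3]),
               c(2L * nd[1] - 1L, nd[2], nd[3]))
    # axis 2
    a <- aperm(array(S2 %*% base::matrix(aperm(a, c(2, 1, 3)), nrow = nd[2]),
                     c(2L * nd[2] - 1L, 2L * nd[1] - 1L, nd[3])), c(2, 1, 3))
    # axis 3
    a <- aperm(array(S3 %*% base::matrix(aperm(a, c(3, 1, 2)), nrow = nd[3]),
                     c(2L * nd[3] - 1L, 2L * nd[1] - 1L, 2L * nd[2] - 1L)),
               c(2, 3, 1))
    out[, , , comp] <- a
  }
  bspline_transform(bsp$grid_origin, bsp$grid_spacing / 2, 2L * nd - 1L, out)
}

#' @export
print.mmdir_affine <- function(x, ...) {
  cat("<mmdir_affine>\n  matrix:\n")
  print(x$matrix)
  cat("  translation:", format(x$translation), "\n")
  invisible(x)
}

#' @export
print.mmdir_bspline <- function(x, ...) {
  cat(sprintf(
    "<mmdir_bspline> grid %s, spacing (%s) mm, max |coef| %.3g mm\n",
    paste(x$grid_dim, collapse = "x"),
    paste(format(x$grid_spacing), collapse = ", "),
    max(abs(x$coefficients))))
  invisible(x)
}

#' @export
print.mmdir_composite <- function(x, ...) {
  cat("<mmdir_composite>\n")
  if (!is.null(x$affine)) print(x$affine) else cat("  (no affine part)\n")
  if (!is.null(x$bspline)) print(x$bspline) else cat("  (no bspline part)\n")
  invisible(x)
}
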