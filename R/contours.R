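# Contour propagation and margin operations.
#
# Margins are physical (mm) and computed with exact Euclidean distance
# transforms rather than voxel structuring elements, because CT voxels here
# are anisotropic (e.g. 5 mm slices vs ~1 mm pixels).

#' Propagate a binary mask through a transform onto a fixed grid
#'
#' With backward-mapping transforms the moving image's content at `T(x)`
#' appears at the fixed-grid location `x`, so the propagated mask is 1 at
#' every fixed voxel center whose mapped position samples the moving mask
#' at or above 0.5 (trilinear interpolation; 0.5 is unbiased for a
#' symmetric interpolator).
#'
#' @param m `mmdir_mask` on the moving grid.
#' @param t transform mapping fixed world to moving world coordinates.
#' @param fixed_geometry an `mmdir_volume` or `mmdir_mask` supplying the
#'   output grid.
#' @return `mmdir_mask` on the fixed grid.
#' @export
propagate_mask <- function(m, t, fixed_geometry) {
  pts <- .voxel_center_points(fixed_geometry)
  y <- apply_transform_points(t, pts)
  vals <- .trilinear_vol(m, y, fill = 0)$value
  out <- array(vals >= 0.5, dim(fixed_geometry$data))
  label_mask(out, spacing = fixed_geometry$spacing,
             origin = fixed_geometry$origin)
}

#' Expand a mask by a physical margin, clipped to a limit region
#'
#' Euclidean-distance-transform dilation: the output contains every voxel
#' whose distance (mm) to the input region is at most `margin_mm`,
#' intersected with `limit` when given. A zero margin with a full limit
#' returns the input unchanged.
#'
#' @param m nonempty `mmdir_mask`.
#' @param margin_mm margin in mm, >= 0.
#' @param limit optional `mmdir_mask` on the same grid (e.g. the body mask,
#'   so expansions stay within the skin surface).
#' @return `mmdir_mask`.
#' @export
expand_margin <- function(m, margin_mm, limit = NULL) {
  if (!any(m$data)) stop("empty mask")
  if (margin_mm < 0) stop("margin must be >= 0")
  d2 <- .cpp_edt_sq(m$data, dim(m$data), m$spacing)
  out <- array(d2 <= margin_mm^2, dim(m$data))
  if (!is.null(limit)) {
    if (!same_geometry(m, limit)) .stop_geometry("mask and limit")
    out <- out & limit$data
  }
  label_mask(out, spacing = m$spacing, origin = m$origin)
}

#' Inner region of a body mask deeper than a given distance from the skin
#'
#' Distance-transform erosion: keeps voxels strictly deeper than `depth_mm`
#' from the body boundary. Used to limit boost-CTV-style expansions to
#' 5 mm from the skin surface.
#'
#' @param body nonempty `mmdir_mask`.
#' @param depth_mm erosion depth in mm, >= 0.
#' @return `mmdir_mask`; errors if the erosion empties the mask.
#' @export
skin_limit_mask <- function(body, depth_mm) {
  if (!any(body$data)) stop("empty mask")
  if (depth_mm < 0) stop("depth must be >= 0")
  if (depth_mm == 0) return(body)
  d2 <- .cpp_edt_sq(!body$data, dim(body$data), body$spacing)
  out <- array(d2 > depth_mm^2 & body$data, dim(body$data))
  if (!any(out)) stop("body thinner than depth")
  label_mask(out, spacing = body$spacing, origin = body$origin)
}
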