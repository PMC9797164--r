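# Quantitative and visual registration assessment: target registration
# error by tissue group, Dice, Hausdorff, checkerboard and orange/cyan
# overlay renderings.

#' Target registration error on held-out landmark pairs
#'
#' Per pair the Euclidean distance `|| x_M - T(x_F) ||` in mm — the moving
#' image's content at `T(x_F)` appears at the fixed location `x_F`, so this
#' measures residual misalignment at each landmark. The pairs must be
#' held-out points never used in the fiducial objective for the result to
#' be an honest error estimate.
#'
#' @param pairs an `mmdir_points` set with group labels.
#' @param transform transform mapping fixed to moving world coordinates.
#' @return An object of class `mmdir_tre`: list with `per_point`
#'   (data.frame: group, distance) and `groups` (data.frame: group, n,
#'   mean, sd).
#' @export
target_registration_error <- function(pairs, transform) {
  if (is.null(pairs) || nrow(pairs$fixed) < 1L) stop("empty point set")
  y <- apply_transform_points(transform, pairs$fixed)
  d <- sqrt(rowSums((pairs$moving - y)^2))
  per_point <- data.frame(group = pairs$group, distance = d,
                          stringsAsFactors = FALSE)
  groups <- do.call(rbind, lapply(split(d, pairs$group), function(v)
    data.frame(n = length(v), mean = mean(v),
               sd = if (length(v) > 1) sd(v) else NA_real_)))
  groups <- data.frame(group = rownames(groups), groups,
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_point = per_point, groups = groups),
            class = "mmdir_tre")
}

#' @export
print.mmdir_tre <- function(x, ...) {
  cat("<mmdir_tre> target registration error (mm)\n")
  g <- x$groups
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %-12s n=%2d  %.2f +/- %s\n", g$group[i], g$n[i],
                g$mean[i],
                ifelse(is.na(g$sd[i]), "NA", sprintf("%.2f", g$sd[i]))))
  invisible(x)
}

#' Dice similarity coefficient between two masks
#'
#' `2|A intersect B| / (|A| + |B|)`, in `[0, 1]`; symmetric in its
#' arguments; undefined (error) when both masks are empty.
#'
#' @param a,b `mmdir_mask` objects on the same grid.
#' @return Dice coefficient.
#' @export
dice <- function(a, b) {
  if (!same_geometry(a, b)) .stop_geometry("masks")
  sa <- sum(a$data); sb <- sum(b$data)
  if (sa + sb == 0) stop("undefined DSC")
  2 * sum(a$data & b$data) / (sa + sb)
}

# Boundary voxels: foreground voxels with at least one 6-neighbor outside
# the mask (array borders count as background).
.boundary_mask <- function(m) {
  d <- dim(m$data)
  x <- m$data
  inner <- array(TRUE, d)
  shift_and <- function(acc, ax, by) {
    idx <- vector("list", 3); for (q in 1:3) idx[[q]] <- seq_len(d[q])
    src <- idx; dst <- idx
    if (by == 1) { dst[[ax]] <- 2:d[ax]; src[[ax]] <- 1:(d[ax] - 1) }
    else { dst[[ax]] <- 1:(d[ax] - 1); src[[ax]] <- 2:d[ax] }
    nb <- array(FALSE, d)
    nb[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
    acc & nb
  }
  for (ax in 1:3) for (by in c(1, -1)) inner <- shift_and(inner, ax, by)
  x & !inner
}

#' Hausdorff distance between two masks (mm)
#'
#' The maximum of the two directed max–min Euclidean distances between the
#' boundary voxels of the masks (6-connectivity erosion difference),
#' computed with exact distance transforms in physical mm.
#'
#' @param a,b nonempty `mmdir_mask` objects on the same grid.
#' @return Hausdorff distance in mm; 0 iff the boundaries coincide.
#' @export
hausdorff <- function(a, b) {
  if (!same_geometry(a, b)) .stop_geometry("masks")
  if (!any(a$data) || !any(b$data)) stop("empty mask")
  ba <- .boundary_mask(a); bb <- .boundary_mask(b)
  da <- .cpp_edt_sq(ba, dim(ba), a$spacing)   # distance to boundary of A
  db <- .cpp_edt_sq(bb, dim(bb), a$spacing)
  h_ab <- sqrt(max(db[ba]))   # farthest boundary-A point from boundary B
  h_ba <- sqrt(max(da[bb]))
  max(h_ab, h_ba)
}

#' Checkerboard composition of two aligned volumes
#'
#' Alternating tiles drawn from the fixed and the (resampled) moving image
#' by the parity of `floor(index / tile)` summed over the three axes;
#' even-parity tiles show the fixed image. Mismatches at high-contrast
#' tissue interfaces show up as broken edges between tiles.
#'
#' @param fixed,moved `mmdir_volume` objects on the same grid.
#' @param tile tile edge length in voxels.
#' @return `mmdir_volume`.
#' @export
checkerboard <- function(fixed, moved, tile = 8) {
  if (!same_geometry(fixed, moved)) .stop_geometry("volumes")
  tile <- as.integer(tile)
  if (tile < 1L) stop("tile must be >= 1 voxel")
  d <- dim(fixed$data)
  i <- (seq_len(d[1]) - 1L) %/% tile
  j <- (seq_len(d[2]) - 1L) %/% tile
  k <- (seq_len(d[3]) - 1L) %/% tile
  parity <- (outer(outer(i, j, "+"), k, "+")) %% 2L
  out <- fixed$data
  out[parity == 1L] <- moved$data[parity == 1L]
  volume(out, spacing = fixed$spacing, origin = fixed$origin)
}

#' Orange/cyan overlay of two aligned volumes
#'
#' The fixed image drives the orange channel weights and the moving image
#' the cyan ones; where the windowed intensities agree the overlay renders
#' gray (R = G = B). Returns an RGB stack (4D array, last dim = 3) with
#' values in `[0, 1]`.
#'
#' @param fixed,moved `mmdir_volume` objects on the same grid.
#' @param window intensity window `c(lo, hi)`; defaults to the fixed
#'   image's range.
#' @return 4D numeric array `c(dim(volume), 3)` of class `mmdir_overlay`.
#' @export
overlay <- function(fixed, moved, window = NULL) {
  if (!same_geometry(fixed, moved)) .stop_geometry("volumes")
  if (is.null(window)) window <- range(fixed$data)
  if (diff(window) <= 0) stop("degenerate window")
  wnd <- function(v) pmin(pmax((v - window[1]) / diff(window), 0), 1)
  wf <- wnd(fixed$data); wm <- wnd(moved$data)
  out <- array(0, c(dim(fixed$data), 3L))
  out[, , , 1] <- wf                  # orange = (1, 0.5, 0)
  out[, , , 2] <- (wf + wm) / 2
  out[, , , 3] <- wm                  # cyan = (0, 0.5, 1)
  structure(out, class = "mmdir_overlay",
            spacing = fixed$spacing, origin = fixed$origin)
}

#' Write one axial slice of an overlay (or volume) as PNG
#'
#' @param x an `mmdir_overlay` or `mmdir_volume`.
#' @param slice 1-based index along the third axis.
#' @param path output `.png` path.
#' @param window intensity window for volumes.
#' @return `path`, invisibly.
#' @export
write_slice_png <- function(x, slice, path, window = NULL) {
  if (inherits(x, "mmdir_overlay")) {
    img <- aperm(x[, , slice, , drop = TRUE][, , 1:3], c(2, 1, 3))
  } else {
    if (is.null(window)) window <- range(x$data)
    sl <- t(pmin(pmax((x$data[, , slice] - window[1]) / diff(window), 0), 1))
    img <- array(sl, c(dim(sl), 3L))
  }
  img <- img[rev(seq_len(nrow(img))), , , drop = FALSE]
  grDevices::png(path, width = ncol(img), height = nrow(img))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::plot.new()
  graphics::rasterImage(img, 0, 0, 1, 1, interpolate = FALSE)
  invisible(path)
}
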