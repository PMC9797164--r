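# Automatic landmark and ROI extraction: 3D Harris corner detection,
# normalized-cross-correlation landmark pairing, and Otsu threshold
# segmentation with connected-component and morphological cleanup. These
# replace the interactive marking/confirmation steps of a clinical
# workflow with automated quality gates.

# Central-difference gradient along one axis, per mm (spacing-aware).
.gradient_axis <- function(a, ax, spacing) {
  d <- dim(a)
  n <- d[ax]
  idx <- lapply(d, seq_len)
  hi <- idx; lo <- idx
  hi[[ax]] <- pmin(idx[[ax]] + 1L, n)
  lo[[ax]] <- pmax(idx[[ax]] - 1L, 1L)
  den <- array(2 * spacing, d)
  # one-sided at the borders
  border <- (hi[[ax]] - lo[[ax]]) == 1L
  if (ax == 1) den[border, , ] <- spacing
  if (ax == 2) den[, border, ] <- spacing
  if (ax == 3) den[, , border] <- spacing
  (do.call(`[`, c(list(a), hi)) - do.call(`[`, c(list(a), lo))) / den
}

# Harris corner response field R = det(M) - k * trace(M)^3.
.harris_response <- function(v, sigma_grad, sigma_window, k) {
  sm <- .smooth_gaussian(v$data, sigma_grad)
  gx <- .gradient_axis(sm, 1, v$spacing[1])
  gy <- .gradient_axis(sm, 2, v$spacing[2])
  gz <- .gradient_axis(sm, 3, v$spacing[3])
  Axx <- .smooth_gaussian(gx * gx, sigma_window)
  Ayy <- .smooth_gaussian(gy * gy, sigma_window)
  Azz <- .smooth_gaussian(gz * gz, sigma_window)
  Axy <- .smooth_gaussian(gx * gy, sigma_window)
  Axz <- .smooth_gaussian(gx * gz, sigma_window)
  Ayz <- .smooth_gaussian(gy * gz, sigma_window)
  detM <- Axx * (Ayy * Azz - Ayz^2) - Axy * (Axy * Azz - Ayz * Axz) +
    Axz * (Axy * Ayz - Ayy * Axz)
  detM - k * (Axx + Ayy + Azz)^3
}

#' 3D Harris corner detection
#'
#' Computes the Gaussian-smoothed structure tensor of the intensity
#' gradients (gradients per mm, so anisotropic slices do not distort the
#' response) and the corner response `R = det(M) - k * trace(M)^3` (the
#' trace-cubed generalization of the 2D detector). Strict local maxima of
#' `R` over the 26-neighborhood with `R > 0` are returned as world
#' coordinates, strongest first.
#'
#' @param v an `mmdir_volume`.
#' @param mask optional `mmdir_mask` restricting the candidate region.
#' @param sigma_grad gradient-smoothing sigma, voxels.
#' @param sigma_window tensor-window sigma, voxels.
#' @param k response parameter.
#' @param n_points maximum number of corners to return.
#' @return N x 3 matrix of world coordinates (possibly fewer than
#'   `n_points` rows; zero rows for a featureless volume).
#' @export
harris_corners_3d <- function(v, mask = NULL, sigma_grad = 1.0,
                              sigma_window = 1.6, k = 0.001,
                              n_points = 30) {
  if (n_points < 1L) stop("n_points must be >= 1")
  d <- dim(v$data)
  if (diff(range(v$data)) == 0) return(base::matrix(0, 0, 3))
  R <- .harris_response(v, sigma_grad, sigma_window, k)
  # strict 26-neighborhood non-maximum suppression (borders excluded)
  keep <- array(TRUE, d)
  keep[c(1, d[1]), , ] <- FALSE
  keep[, c(1, d[2]), ] <- FALSE
  keep[, , c(1, d[3])] <- FALSE
  if (!is.null(mask)) {
    if (!same_geometry(v, mask)) .stop_geometry("volume and mask")
    keep <- keep & mask$data
  }
  keep <- keep & (R > 0)
  cand <- which(keep)
  if (length(cand) == 0) return(base::matrix(0, 0, 3))
  ii <- arrayInd(cand, d)
  for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    nb <- cand + di + d[1] * dj + d[1] * d[2] * dk
    ok <- R[cand] > R[nb]
    cand <- cand[ok]; ii <- ii[ok, , drop = FALSE]
    if (length(cand) == 0) return(base::matrix(0, 0, 3))
  }
  ord <- order(R[cand], decreasing = TRUE)
  ord <- ord[seq_len(min(n_points, length(ord)))]
  voxel_to_world(v, ii[ord, , drop = FALSE] - 1)
}

#' Pair landmarks across images by local correlation search
#'
#' For each fixed-image point, searches the moving image over a voxel
#' lattice of candidate displacements (within `search_radius_mm`) for the
#' position maximizing the normalized cross-correlation of an intensity
#' patch (`patch_radius_mm`). Pairs whose peak correlation falls below
#' `min_corr`, or whose match would leave the moving volume, are dropped —
#' the automated stand-in for interactive confirmation of pairings.
#'
#' @param fixed,moving `mmdir_volume` objects.
#' @param fixed_pts N x 3 matrix of world points inside the fixed volume.
#' @param search_radius_mm search radius, mm.
#' @param patch_radius_mm patch radius, mm.
#' @param min_corr minimum acceptable peak correlation.
#' @param initial_transform optional transform (e.g. the affine stage)
#'   centering each search.
#' @param max_inconsistency_mm drop matches whose displacement deviates
#'   from the median of their five nearest neighbors' displacements by
#'   more than this (the deformation being estimated is smooth);
#'   `Inf` disables the gate.
#' @return An `mmdir_points` set of the surviving pairs; errors with
#'   "no reliable pairs" when none survive.
#' @export
match_points <- function(fixed, moving, fixed_pts, search_radius_mm = 10,
                         patch_radius_mm = 6, min_corr = 0.6,
                         initial_transform = NULL,
                         max_inconsistency_mm = 6) {
  fixed_pts <- .as_points(fixed_pts)
  lattice <- function(spacing, radius, stride = c(1L, 1L, 1L)) {
    r <- floor(radius / (spacing * stride))
    g <- as.matrix(expand.grid(x = -r[1]:r[1], y = -r[2]:r[2],
                               z = -r[3]:r[3]))
    g <- sweep(g, 2, stride, "*")
    off <- sweep(g, 2, spacing, "*")
    keep <- rowSums(off^2) <= radius^2
    g[keep, , drop = FALSE]
  }
  offs <- sweep(lattice(fixed$spacing, patch_radius_mm), 2,
                fixed$spacing, "*")
  # stride 2 in-plane only: through-plane spacing is coarse already and
  # correlation peaks are narrow
  g_coarse <- lattice(moving$spacing, search_radius_mm,
                      stride = c(2L, 2L, 1L))
  g_fine <- as.matrix(expand.grid(x = -2:2, y = -2:2, z = -1:1))
  centers <- if (is.null(initial_transform)) fixed_pts else
    apply_transform_points(initial_transform, fixed_pts)

  # NCC of the (zero-mean) fixed patch against moving patches at the given
  # integer-voxel displacements; NA where the moving patch leaves the grid
  ncc_at <- function(fz, center, g) {
    base_pts <- sweep(sweep(g, 2, moving$spacing, "*"), 2, center, "+")
    nC <- nrow(g); nO <- nrow(offs)
    big <- base_pts[rep(seq_len(nC), each = nO), , drop = FALSE] +
      offs[rep(seq_len(nO), nC), , drop = FALSE]
    V <- base::matrix(.trilinear_vol(moving, big, fill = NA)$value, nO, nC)
    corr <- rep(NA_real_, nC)
    okc <- colSums(is.na(V)) == 0
    if (!any(okc)) return(corr)
    Vc <- V[, okc, drop = FALSE]
    Vz <- sweep(Vc, 2, colMeans(Vc))
    den <- sqrt(colSums(Vz^2) * sum(fz^2))
    corr[okc] <- ifelse(den > 0, colSums(Vz * fz) / den, -Inf)
    corr
  }

  keep_f <- list(); keep_m <- list()
  for (i in seq_len(nrow(fixed_pts))) {
    p <- fixed_pts[i, ]
    fpatch <- .trilinear_vol(fixed, sweep(offs, 2, p, "+"),
                             fill = NA)$value
    if (anyNA(fpatch) || sd(fpatch) == 0) next
    fz <- fpatch - mean(fpatch)
    # stage 1: stride-2 sweep of the search region
    c1 <- ncc_at(fz, centers[i, ], g_coarse)
    if (all(is.na(c1) | !is.finite(c1))) next
    g_best <- g_coarse[which.max(ifelse(is.na(c1), -Inf, c1)), ]
    # stage 2: full-resolution 3x3x3 refinement around the coarse peak
    g2 <- sweep(g_fine, 2, g_best, "+")
    c2 <- ncc_at(fz, centers[i, ], g2)
    i2 <- which.max(ifelse(is.na(c2), -Inf, c2))
    if (!is.finite(c2[i2]) || is.na(c2[i2]) || c2[i2] < min_corr) next
    mpt <- centers[i, ] + g2[i2, ] * moving$spacing
    # sub-voxel parabolic refinement per axis (skipped at a perfect peak)
    for (ax in if (c2[i2] >= 1 - 1e-9) integer(0) else 1:3) {
      gm <- g2[i2, ]; gp <- gm; gm[ax] <- gm[ax] - 1L; gp[ax] <- gp[ax] + 1L
      im <- which(g2[, 1] == gm[1] & g2[, 2] == gm[2] & g2[, 3] == gm[3])
      ip <- which(g2[, 1] == gp[1] & g2[, 2] == gp[2] & g2[, 3] == gp[3])
      if (length(im) != 1L || length(ip) != 1L) next
      cm <- c2[im]; cp <- c2[ip]; cc <- c2[i2]
      den <- cm - 2 * cc + cp
      if (anyNA(c(cm, cp)) || !is.finite(den) || den >= -1e-12) next
      delta <- max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
      mpt[ax] <- mpt[ax] + delta * moving$spacing[ax]
    }
    keep_f[[length(keep_f) + 1L]] <- p
    keep_m[[length(keep_m) + 1L]] <- mpt
  }
  if (length(keep_f) == 0) stop("no reliable pairs")
  pf <- do.call(rbind, keep_f); pm <- do.call(rbind, keep_m)
  # consistency gate: the sought deformation is smooth, so a match whose
  # displacement deviates strongly from its neighbors' median is spurious
  if (is.finite(max_inconsistency_mm) && nrow(pf) >= 5L) {
    disp <- pm - pf
    ok <- vapply(seq_len(nrow(pf)), function(i) {
      dd <- sqrt(rowSums(sweep(pf, 2, pf[i, ])^2))
      nb <- order(dd)[2:min(6, nrow(pf))]
      med <- apply(disp[nb, , drop = FALSE], 2, median)
      sqrt(sum((disp[i, ] - med)^2)) <= max_inconsistency_mm
    }, TRUE)
    if (!any(ok)) stop("no reliable pairs")
    pf <- pf[ok, , drop = FALSE]; pm <- pm[ok, , drop = FALSE]
  }
  paired_points(pf, pm)
}

# Otsu threshold on a value vector: maximizes between-class variance over
# `n_bins` histogram bin edges; returns the threshold value.
.otsu_threshold <- function(vals, n_bins = 256) {
  r <- range(vals)
  if (diff(r) == 0) stop("degenerate histogram")
  h <- tabulate(pmin(floor((vals - r[1]) / diff(r) * n_bins), n_bins - 1) +
                  1L, n_bins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(n_bins) - 0.5) * diff(r) / n_bins
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu0)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  t_idx <- which.max(between)
  r[1] + t_idx * diff(r) / n_bins   # upper edge of the argmax bin
}

#' Automatic gray-level threshold segmentation
#'
#' Otsu threshold on the (optionally masked) intensity histogram;
#' foreground = voxels strictly above the threshold, reduced to the
#' largest 26-connected component and optionally closed with a physical
#' (mm) radius. Components smaller than `min_volume_mm3` are rejected —
#' the automated stand-in for interactive confirmation of the contour.
#'
#' @param v an `mmdir_volume`.
#' @param mask optional `mmdir_mask` restricting the histogram and output.
#' @param n_bins histogram bins for the threshold search.
#' @param closing_mm morphological closing radius, mm (0 = none).
#' @param min_volume_mm3 minimum acceptable component volume.
#' @return An `mmdir_mask`.
#' @export
threshold_segment <- function(v, mask = NULL, n_bins = 256, closing_mm = 0,
                              min_volume_mm3 = 0) {
  d <- dim(v$data)
  inside <- if (is.null(mask)) array(TRUE, d) else {
    if (!same_geometry(v, mask)) .stop_geometry("volume and mask")
    mask$data
  }
  vals <- v$data[inside]
  if (length(vals) == 0 || diff(range(vals)) == 0)
    stop("degenerate histogram")
  thr <- .otsu_threshold(vals, n_bins)
  fg <- array(v$data > thr & inside, d)
  if (!any(fg)) stop("empty segmentation")
  lab <- array(.cpp_label_components(fg, d), d)
  sizes <- tabulate(lab[lab > 0])
  biggest <- which.max(sizes)
  fg <- lab == biggest
  if (sizes[biggest] * prod(v$spacing) < min_volume_mm3)
    stop("largest component below minimum volume")
  if (closing_mm > 0) {
    dil <- array(.cpp_edt_sq(fg, d, v$spacing) <= closing_mm^2, d)
    fg <- array(.cpp_edt_sq(!dil, d, v$spacing) > closing_mm^2, d)
  }
  label_mask(array(fg, d), spacing = v$spacing, origin = v$origin)
}
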