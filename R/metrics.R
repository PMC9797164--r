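# The three registration cost terms and their weighted combination.
#
# Sign convention: every metric is MINIMIZED. Similarity measures enter
# negated: the region term is (1 - KS), the intensity term is -MI. The
# combined objective is the weight-normalized sum
#   C = (1 / sum(w_i)) * sum(w_i * C_i)
# with C_1 the fiducial term (mean Euclidean distance, mm), C_2 the region
# term and C_3 the intensity term.
#
# Each metric returns list(value, gradient, ...) where `gradient` (optional)
# is the analytic derivative with respect to the B-spline coefficients of
# the transform, an array of dim c(grid_dim, 3).

#' Metric weights for the combined objective
#'
#' Defaults to the fiducial/region/intensity weighting (1, 1, 100) found to
#' work best by trial and error in the source study.
#'
#' @param fiducial,region,intensity non-negative weights; at least one must
#'   be positive.
#' @return An object of class `mmdir_weights`.
#' @export
metric_weights <- function(fiducial = 1, region = 1, intensity = 100) {
  w <- c(fiducial = as.double(fiducial), region = as.double(region),
         intensity = as.double(intensity))
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be >= 0")
  if (all(w == 0)) stop("at least one metric weight must be positive")
  structure(w, class = "mmdir_weights")
}

#' Mutual-information estimator settings
#'
#' @param n_bins intensity bins per image (at least 2; the Parzen mode
#'   needs at least 5 because the cubic kernel reserves two guard bins
#'   per side).
#' @param n_samples voxel samples per stochastic evaluation.
#' @param range_quantiles per-image robust intensity range, as lower/upper
#'   quantiles; keeps bright outliers (surgical clips) from crushing the
#'   histogram.
#' @param fixed_range,moving_range optional explicit `[min, max]` intensity
#'   ranges, normally computed once per resolution level.
#' @return An object of class `mmdir_mi_config`.
#' @export
mi_config <- function(n_bins = 32, n_samples = 2048,
                      range_quantiles = c(0.005, 0.995),
                      fixed_range = NULL, moving_range = NULL) {
  n_bins <- as.integer(n_bins); n_samples <- as.integer(n_samples)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (n_samples < 1L) stop("n_samples must be >= 1")
  structure(list(n_bins = n_bins, n_samples = n_samples,
                 range_quantiles = as.double(range_quantiles),
                 fixed_range = fixed_range, moving_range = moving_range),
            class = "mmdir_mi_config")
}

# Chain dCost/dT(x) (N x 3) through the B-spline weights to dCost/dmu.
.chain_to_mu <- function(t, pts, dcdpos) {
  b <- .bspline_part(t)
  if (is.null(b))
    stop("transform has no B-spline part to differentiate")
  array(.cpp_bspline_grad_accum(pts, b$grid_origin, b$grid_spacing,
                                b$grid_dim, dcdpos),
        c(b$grid_dim, 3L))
}

.trilinear_vol <- function(v, pts, want_grad = FALSE, fill = 0) {
  dat <- v$data
  if (is.logical(dat)) dat <- array(as.double(dat), dim(dat))
  .cpp_trilinear(dat, dim(v$data), v$spacing, v$origin, pts, want_grad, fill)
}

# ------------------------------------------------------------- fiducial

#' Fiducial cost: mean Euclidean distance between paired landmarks
#'
#' `mean_i || x_M_i - T(x_F_i) ||` in mm. Zero exactly when every
#' transformed fixed point coincides with its moving partner.
#'
#' @param transform transform mapping fixed to moving world coordinates.
#' @param pairs an `mmdir_points` set (P >= 1).
#' @param gradient also return the analytic gradient with respect to the
#'   B-spline coefficients of `transform`.
#' @return `list(value, gradient)`; `value` in mm.
#' @export
fiducial_cost <- function(transform, pairs, gradient = FALSE) {
  if (is.null(pairs) || !inherits(pairs, "mmdir_points") ||
      nrow(pairs$fixed) < 1L)
    stop("no fiducial pairs")
  y <- apply_transform_points(transform, pairs$fixed)
  diff <- pairs$moving - y
  d <- sqrt(rowSums(diff^2))
  out <- list(value = mean(d), per_point = d)
  if (gradient) {
    P <- length(d)
    scale <- ifelse(d > 0, 1 / (P * d), 0)
    dcdpos <- -diff * scale
    out$gradient <- .chain_to_mu(transform, pairs$fixed, dcdpos)
  }
  out
}

# --------------------------------------------------------------- region

# Fixed-grid sample support for the region term: voxel centers within
# `dilate_mm` of the fixed ROI (Euclidean distance transform).
.kappa_support <- function(roi_fixed, dilate_mm) {
  d2 <- .cpp_edt_sq(roi_fixed$data, dim(roi_fixed$data), roi_fixed$spacing)
  which(d2 <= dilate_mm^2) - 1L
}

#' Region cost: one minus the (soft) Kappa overlap statistic
#'
#' The Kappa statistic `KS = 2|A & B| / (|A| + |B|)` is made differentiable
#' by sampling the moving binary mask at `T(x)` with trilinear interpolation
#' (values in `[0, 1]`) over fixed-grid sample points near the fixed ROI.
#' The returned cost is `1 - KS`, 0 for perfect overlap, 1 for disjoint
#' regions. Use [kappa_statistic()] for the hard (0.5-thresholded) value
#' used in reports.
#'
#' @param transform transform mapping fixed to moving world coordinates.
#' @param roi_fixed,roi_moving nonempty `mmdir_mask` objects (grids may
#'   differ).
#' @param gradient also return the analytic gradient w.r.t. the B-spline
#'   coefficients.
#' @param samples optional N x 3 matrix of fixed-world sample points (used
#'   by the stochastic optimizer); default: all voxel centers within
#'   `dilate_mm` of the fixed ROI.
#' @param sample_values optional fixed-mask values at `samples`.
#' @param dilate_mm support margin around the fixed ROI, mm.
#' @return `list(value, ks, gradient)`.
#' @export
kappa_cost <- function(transform, roi_fixed, roi_moving, gradient = FALSE,
                       samples = NULL, sample_values = NULL,
                       dilate_mm = 12) {
  if (!inherits(roi_fixed, "mmdir_mask") || !inherits(roi_moving, "mmdir_mask"))
    stop("ROIs must be mmdir_mask objects")
  if (!any(roi_fixed$data) || !any(roi_moving$data)) stop("empty ROI")
  if (is.null(samples)) {
    idx <- .kappa_support(roi_fixed, dilate_mm)
    samples <- .voxel_center_points(roi_fixed, idx)
    sample_values <- as.double(roi_fixed$data[idx + 1L])
  } else {
    samples <- .as_points(samples)
    if (is.null(sample_values))
      sample_values <- .trilinear_vol(roi_fixed, samples)$value
  }
  A <- sample_values
  y <- apply_transform_points(transform, samples)
  mv <- .trilinear_vol(roi_moving, y, want_grad = gradient, fill = 0)
  B <- mv$value
  r <- .kappa_core(A, B, want_grad = gradient)
  out <- list(value = r$value, ks = r$ks)
  if (gradient)
    out$gradient <- .chain_to_mu(transform, samples, mv$grad * r$dcdB)
  out
}

# Soft-Kappa cost core: fixed-mask values A, interpolated moving-mask
# values B at the mapped sample points. dcdB is d(1 - KS)/dB per sample.
.kappa_core <- function(A, B, want_grad = FALSE) {
  SA <- sum(A); SB <- sum(B); SAB <- sum(A * B)
  D <- SA + SB
  if (D == 0)
    return(list(value = 1, ks = 0,
                dcdB = if (want_grad) double(length(A)) else NULL))
  KS <- 2 * SAB / D
  list(value = 1 - KS, ks = KS,
       dcdB = if (want_grad) -(2 * A - KS) / D else NULL)
}

#' Hard Kappa statistic between a fixed ROI and a transformed moving ROI
#'
#' Propagates the moving mask onto the fixed grid through `transform`
#' (trilinear, 0.5 threshold) and evaluates `2|A & B| / (|A| + |B|)`.
#'
#' @inheritParams kappa_cost
#' @return Kappa statistic in `[0, 1]`.
#' @export
kappa_statistic <- function(transform, roi_fixed, roi_moving) {
  if (!any(roi_fixed$data) || !any(roi_moving$data)) stop("empty ROI")
  moved <- propagate_mask(roi_moving, transform, roi_fixed)
  A <- roi_fixed$data; B <- moved$data
  2 * sum(A & B) / (sum(A) + sum(B))
}

# ------------------------------------------------------------ intensity

.intensity_range <- function(v, q) {
  r <- unname(quantile(v$data, probs = q, names = FALSE, type = 7))
  if (!is.finite(diff(r))) stop("cannot determine intensity range")
  r
}

#' Mutual information cost between fixed and moving intensities
#'
#' Estimates the mutual information (bits, base-2 logarithm) of the joint
#' intensity distribution of the fixed image and the transformed moving
#' image, and returns its negation so the metric is minimized.
#'
#' Two estimators are available:
#' \describe{
#'   \item{`"parzen"`}{Stochastic sampling of fixed-domain voxels; hard
#'     (zero-order) binning on the fixed axis and a cubic B-spline Parzen
#'     window on the moving axis. Differentiable; used by the optimizer.}
#'   \item{`"dense"`}{Hard binning on both axes over all (or the supplied)
#'     sample points. Deterministic and exact; used for reporting and as an
#'     oracle target in tests. No gradient.}
#' }
#'
#' @param transform transform mapping fixed to moving world coordinates.
#' @param fixed,moving `mmdir_volume` objects.
#' @param cfg an [mi_config()].
#' @param mode `"parzen"` or `"dense"`.
#' @param samples optional N x 3 matrix of fixed-world sample points;
#'   default: `cfg$n_samples` random voxel centers (parzen) or all voxel
#'   centers (dense).
#' @param seed RNG seed for sample drawing (parzen mode).
#' @param gradient also return the analytic gradient w.r.t. the B-spline
#'   coefficients (parzen mode only).
#' @param fixed_mask optional `mmdir_mask` restricting the sampled region
#'   (e.g. a body mask, so air does not dilute the histogram).
#' @return `list(value, mi, n_valid, gradient)`; `value = -mi` in bits.
#' @export
mutual_information <- function(transform, fixed, moving, cfg = mi_config(),
                               mode = c("parzen", "dense"), samples = NULL,
                               seed = NULL, gradient = FALSE,
                               fixed_mask = NULL) {
  mode <- match.arg(mode)
  nb <- cfg$n_bins
  if (mode == "parzen" && nb < 5L)
    stop("parzen mode needs n_bins >= 5")
  if (gradient && mode == "dense")
    stop("gradient requires parzen mode")
  if (is.null(samples)) {
    cand <- if (!is.null(fixed_mask)) {
      if (!same_geometry(fixed, fixed_mask)) .stop_geometry("mask and volume")
      which(fixed_mask$data) - 1L
    } else seq_len(length(fixed$data)) - 1L
    if (mode == "dense") {
      samples <- .voxel_center_points(fixed, cand)
    } else {
      if (!is.null(seed)) set.seed(seed)
      take <- sample(length(cand), min(cfg$n_samples, length(cand)))
      samples <- .voxel_center_points(fixed, cand[take])
    }
  } else samples <- .as_points(samples)

  fv <- .trilinear_vol(fixed, samples)
  y <- apply_transform_points(transform, samples)
  mv <- .trilinear_vol(moving, y, want_grad = gradient)
  valid <- fv$inside & mv$inside
  nvalid <- sum(valid)
  if (nvalid < nb) stop("insufficient overlap")

  f <- fv$value[valid]
  m <- mv$value[valid]
  fr <- if (!is.null(cfg$fixed_range)) as.double(cfg$fixed_range) else
    .intensity_range(fixed, cfg$range_quantiles)
  mr <- if (!is.null(cfg$moving_range)) as.double(cfg$moving_range) else
    .intensity_range(moving, cfg$range_quantiles)
  zero_grad <- function() {
    if (!gradient) return(NULL)
    .chain_to_mu(transform, samples, matrix(0, nrow(samples), 3))
  }
  if (diff(fr) <= 0 || diff(mr) <= 0) {
    # a degenerate (constant) image carries no information
    return(list(value = 0, mi = 0, n_valid = nvalid, gradient = zero_grad()))
  }

  if (mode == "dense") {
    fw <- diff(fr) / nb
    fb <- pmin(pmax(floor((f - fr[1]) / fw), 0), nb - 1)
    mw <- diff(mr) / nb
    mb <- pmin(pmax(floor((m - mr[1]) / mw), 0), nb - 1)
    P <- base::matrix(0, nb, nb)
    P[] <- tabulate(fb + nb * mb + 1L, nbins = nb * nb) / nvalid
    mi <- .mi_from_joint(P)
    return(list(value = -mi, mi = mi, n_valid = nvalid))
  }
  r <- .mi_parzen_core(f, m, fr, mr, nb, want_grad = gradient)
  out <- list(value = r$value, mi = r$mi, n_valid = nvalid)
  if (gradient) {
    dcdm <- double(nrow(samples))
    dcdm[valid] <- r$dcdm
    out$gradient <- .chain_to_mu(transform, samples, mv$grad * dcdm)
  }
  out
}

# MI (bits) of a joint probability table.
.mi_from_joint <- function(P) {
  pF <- rowSums(P); pM <- colSums(P)
  pos <- P > 0
  sum(P[pos] * log2(P[pos] / (pF[row(P)[pos]] * pM[col(P)[pos]])))
}

# Parzen MI core over valid samples: returns -MI and (optionally) its
# derivative with respect to each moving intensity sample.
.mi_parzen_core <- function(f, m, fr, mr, nb, want_grad = FALSE) {
  nvalid <- length(m)
  fw <- diff(fr) / nb
  fb <- pmin(pmax(floor((f - fr[1]) / fw), 0), nb - 1)
  s <- (nb - 4) / diff(mr)
  tm <- 1 + (pmin(pmax(m, mr[1]), mr[2]) - mr[1]) * s
  base_bin <- floor(tm)
  P <- base::matrix(0, nb, nb)
  for (off in -1:2) {
    bin <- base_bin + off
    acc <- rowsum(.cpp_bspl3(tm - bin), group = fb + nb * bin)
    ii <- as.integer(rownames(acc)) + 1L
    P[ii] <- P[ii] + acc[, 1]
  }
  P <- P / nvalid
  pF <- rowSums(P); pM <- colSums(P)
  pos <- P > 0
  L <- base::matrix(0, nb, nb)
  L[pos] <- log2(P[pos] / (pF[row(P)[pos]] * pM[col(P)[pos]]))
  mi <- sum(P[pos] * L[pos])
  dcdm <- NULL
  if (want_grad) {
    dmi_dm <- double(nvalid)
    for (off in -1:2) {
      bin <- base_bin + off
      dmi_dm <- dmi_dm + .cpp_bspl3_deriv(tm - bin) * L[fb + nb * bin + 1L]
    }
    sj <- ifelse(m >= mr[1] & m <= mr[2], s, 0)
    dcdm <- -dmi_dm * sj / nvalid
  }
  list(value = -mi, mi = mi, dcdm = dcdm)
}

# ------------------------------------------------------------- combined

#' Weighted multi-metric objective
#'
#' `C = sum(w_i C_i) / sum(w_i)` over the fiducial, region and intensity
#' costs. With exactly one nonzero weight the result equals that
#' component's cost exactly. Metrics with zero weight are skipped and do
#' not need their inputs.
#'
#' @param transform transform mapping fixed to moving world coordinates.
#' @param inputs named list with (as needed) `pairs`, `roi_fixed`,
#'   `roi_moving`, `fixed`, `moving`, `fixed_mask`.
#' @param weights an [metric_weights()] vector.
#' @param cfg an [mi_config()].
#' @param gradient also return the gradient w.r.t. B-spline coefficients.
#' @param mi_mode `"parzen"` or `"dense"` for the intensity term.
#' @param mi_samples,kappa_samples,kappa_values optional precomputed sample
#'   points (see [mutual_information()], [kappa_cost()]).
#' @param seed RNG seed for MI sampling when `mi_samples` is absent.
#' @param dilate_mm support margin for the region term.
#' @return `list(value, components, gradient)`; `components` is the named
#'   vector of per-metric costs (NA for zero-weight metrics).
#' @export
combined_cost <- function(transform, inputs, weights = metric_weights(),
                          cfg = mi_config(), gradient = FALSE,
                          mi_mode = "parzen", mi_samples = NULL,
                          kappa_samples = NULL, kappa_values = NULL,
                          seed = NULL, dilate_mm = 12) {
  if (!inherits(weights, "mmdir_weights")) weights <- do.call(metric_weights, as.list(weights))
  w <- unclass(weights)
  if (all(w == 0)) stop("all weights zero")
  comps <- c(fiducial = NA_real_, region = NA_real_, intensity = NA_real_)
  grads <- list()
  if (w["fiducial"] > 0) {
    if (is.null(inputs$pairs))
      stop("fiducial metric requires 'pairs' input")
    r <- fiducial_cost(transform, inputs$pairs, gradient = gradient)
    comps["fiducial"] <- r$value; grads$fiducial <- r$gradient
  }
  if (w["region"] > 0) {
    if (is.null(inputs$roi_fixed) || is.null(inputs$roi_moving))
      stop("region metric requires 'roi_fixed' and 'roi_moving' inputs")
    r <- kappa_cost(transform, inputs$roi_fixed, inputs$roi_moving,
                    gradient = gradient, samples = kappa_samples,
                    sample_values = kappa_values, dilate_mm = dilate_mm)
    comps["region"] <- r$value; grads$region <- r$gradient
  }
  if (w["intensity"] > 0) {
    if (is.null(inputs$fixed) || is.null(inputs$moving))
      stop("intensity metric requires 'fixed' and 'moving' inputs")
    r <- mutual_information(transform, inputs$fixed, inputs$moving,
                            cfg = cfg, mode = mi_mode, samples = mi_samples,
                            seed = seed, gradient = gradient,
                            fixed_mask = inputs$fixed_mask)
    comps["intensity"] <- r$value; grads$intensity <- r$gradient
  }
  nz <- names(w)[w > 0]
  if (length(nz) == 1L) {
    value <- comps[[nz]]
    grad <- if (gradient) grads[[nz]] else NULL
  } else {
    value <- sum(w[nz] * comps[nz]) / sum(w)
    grad <- NULL
    if (gradient) {
      grad <- grads[[nz[1]]] * (w[[nz[1]]] / sum(w))
      for (k in nz[-1]) grad <- grad + grads[[k]] * (w[[k]] / sum(w))
    }
  }
  list(value = value, components = comps, gradient = grad)
}
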