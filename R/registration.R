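# Registration orchestration: affine initialization, 3-level Gaussian
# pyramid, per-level B-spline grid refinement, stochastic gradient descent
# on the weighted multi-metric objective.

#' Registration settings
#'
#' @param levels number of pyramid levels (>= 1).
#' @param factors per-level downsampling factors, coarse to fine; the
#'   finest must be 1.
#' @param sigmas per-level Gaussian smoothing, in voxels; default
#'   `factors / 2` (standard anti-aliasing).
#' @param grid_spacing per-level B-spline control spacing in mm, strictly
#'   halving coarse to fine (so between-level coefficient transfer is exact
#'   dyadic refinement). Default `NULL`: the finest spacing is chosen as
#'   (largest domain extent) / `n_grid`, i.e. about `n_grid` control
#'   intervals across the image, with the coarser levels at 4x and 2x.
#' @param n_grid target number of finest-level control intervals across the
#'   largest image extent (used when `grid_spacing` is `NULL`).
#' @param max_iter iteration cap per resolution level.
#' @param sgd_A,sgd_alpha gain-sequence parameters of
#'   `gamma_t = a / (t + A)^alpha`.
#' @param step0 desired first-iteration parameter step (mm); the gain
#'   scale `a` is derived from it and the initial gradient.
#' @param tol early-stop tolerance on the gradient norm.
#' @param weights an [metric_weights()] vector.
#' @param mi an [mi_config()]; the registration default uses 64 bins
#'   (finer than the standalone estimator default) so that low-contrast
#'   soft-tissue texture is resolved by the joint histogram.
#' @param kappa_samples region-term samples per iteration.
#' @param dilate_mm region-term support margin (mm).
#' @param do_affine run the affine initialization stage.
#' @param affine_samples fixed sample count for the affine stage.
#' @param seed integer seed controlling every stochastic choice.
#' @return An object of class `mmdir_config` (a named list).
#' @export
registration_config <- function(levels = 3, factors = c(4, 2, 1),
                                sigmas = NULL, grid_spacing = NULL,
                                n_grid = 12, max_iter = 500,
                                sgd_A = 50, sgd_alpha = 0.602, step0 = 2,
                                tol = 1e-6, weights = metric_weights(),
                                mi = mi_config(n_bins = 64),
                                kappa_samples = 2048,
                                dilate_mm = 12, do_affine = TRUE,
                                affine_samples = 4000, seed = 1) {
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  factors <- as.double(factors)
  if (length(factors) != levels || any(factors < 1) ||
      factors[levels] != 1 || is.unsorted(rev(factors)))
    stop("factors must be non-increasing and end at 1")
  if (is.null(sigmas)) sigmas <- factors / 2
  if (length(sigmas) != levels) stop("need one sigma per level")
  if (!is.null(grid_spacing)) {
    grid_spacing <- as.double(grid_spacing)
    if (length(grid_spacing) != levels)
      stop("need one control spacing per level")
    if (levels > 1 && any(abs(grid_spacing[-levels] / grid_spacing[-1] - 2)
                          > 1e-9))
      stop("control spacing must halve between levels")
  }
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (!inherits(weights, "mmdir_weights"))
    weights <- do.call(metric_weights, as.list(weights))
  structure(list(levels = levels, factors = factors, sigmas = sigmas,
                 grid_spacing = grid_spacing, n_grid = as.double(n_grid),
                 max_iter = as.integer(max_iter), sgd_A = sgd_A,
                 sgd_alpha = sgd_alpha, step0 = step0, tol = tol,
                 weights = weights, mi = mi,
                 kappa_samples = as.integer(kappa_samples),
                 dilate_mm = dilate_mm, do_affine = isTRUE(do_affine),
                 affine_samples = as.integer(affine_samples),
                 seed = as.integer(seed)),
            class = "mmdir_config")
}

# Control-spacing schedule for a given fixed image.
.grid_schedule <- function(cfg, fixed) {
  if (!is.null(cfg$grid_spacing)) return(cfg$grid_spacing)
  dom <- .domain_of(fixed)
  finest <- max(dom$hi - dom$lo) / cfg$n_grid
  finest * 2^((cfg$levels - 1):0)
}

# Separable Gaussian smoothing, sigma in voxels (length 1 or 3), sampled
# kernel truncated at 4 sigma, whole-sample reflection at the borders.
.smooth_gaussian <- function(arr, sigma) {
  sigma <- rep(sigma, length.out = 3)
  d <- dim(arr)
  smooth_axis <- function(a, ax, s) {
    if (s <= 0) return(a)
    n <- dim(a)[ax]
    r <- max(1L, ceiling(4 * s))
    k <- dnorm(seq(-r, r), sd = s); k <- k / sum(k)
    S <- base::matrix(0, n, n)
    for (o in seq(-r, r)) {
      j <- seq_len(n) + o
      j <- ifelse(j < 1L, 2L - j, ifelse(j > n, 2L * n - j, j))
      j <- pmin(pmax(j, 1L), n)
      S[cbind(seq_len(n), j)] <- S[cbind(seq_len(n), j)] + k[o + r + 1]
    }
    if (ax == 1) {
      array(S %*% base::matrix(a, d[1]), d)
    } else if (ax == 2) {
      aperm(array(S %*% base::matrix(aperm(a, c(2, 1, 3)), d[2]),
                  d[c(2, 1, 3)]), c(2, 1, 3))
    } else {
      aperm(array(S %*% base::matrix(aperm(a, c(3, 1, 2)), d[3]),
                  d[c(3, 1, 2)]), c(2, 3, 1))
    }
  }
  for (ax in 1:3) arr <- smooth_axis(arr, ax, sigma[ax])
  arr
}

#' Gaussian pyramid of a volume
#'
#' Level `k` is the input smoothed with `sigmas[k]` (voxels) and resampled
#' at every `factors[k]`-th voxel, so spacing scales by the factor while
#' the origin is unchanged and the world extent is preserved to within one
#' coarse voxel.
#'
#' @param v an `mmdir_volume`.
#' @param levels,sigmas,factors see [registration_config()].
#' @return List of `mmdir_volume`, coarse to fine.
#' @export
gaussian_pyramid <- function(v, levels = 3, sigmas = NULL,
                             factors = c(4, 2, 1)) {
  if (is.null(sigmas)) sigmas <- factors / 2
  stopifnot(length(factors) == levels, length(sigmas) == levels)
  d <- dim(v$data)
  lapply(seq_len(levels), function(k) {
    f <- factors[k]
    sm <- .smooth_gaussian(v$data, sigmas[k])
    if (f == 1) return(volume(sm, v$spacing, v$origin))
    idx <- lapply(d, function(n) seq(1L, n, by = f))
    volume(sm[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
           spacing = v$spacing * f, origin = v$origin)
  })
}

#' Stochastic gradient descent with a decaying gain sequence
#'
#' Gain `gamma_t = a / (t + A)^alpha`, `t = 0, 1, ...`; when `a` is not
#' given it is auto-scaled so the first step has infinity-norm `step0`.
#' Deterministic given the seed handling of `cost_fn` (the optimizer itself
#' draws no random numbers).
#'
#' @param cost_fn `function(params, iter)` returning
#'   `list(value, gradient)`.
#' @param init initial parameter vector.
#' @param max_iter iteration cap.
#' @param a,A,alpha gain parameters (`a = NULL` auto-scales from `step0`).
#' @param step0 target first-step size when auto-scaling `a`.
#' @param tol early stop when the gradient Euclidean norm drops below it.
#' @return `list(par, trace, iterations)`.
#' @export
sgd_minimize <- function(cost_fn, init, max_iter = 500, a = NULL, A = 50,
                         alpha = 0.602, step0 = 2, tol = 1e-6) {
  par <- as.double(init)
  trace <- double(0)
  for (it in seq_len(max_iter)) {
    r <- cost_fn(par, it)
    g <- as.double(r$gradient)
    if (!is.finite(r$value) || any(!is.finite(g)))
      stop(sprintf("non-finite cost or gradient at iteration %d", it))
    trace[it] <- r$value
    gn <- sqrt(sum(g^2))
    if (gn < tol) return(list(par = par, trace = trace, iterations = it))
    if (is.null(a)) a <- step0 * (A + 1)^alpha / max(abs(g))
    gamma <- a / (it - 1 + A)^alpha
    par <- par - gamma * g
  }
  list(par = par, trace = trace, iterations = max_iter)
}

# Center-of-mass of above-background intensity, in world mm.
.center_of_mass <- function(v) {
  w <- v$data - min(v$data)
  s <- sum(w)
  if (s == 0) return(v$origin + (dim(v$data) - 1) * v$spacing / 2)
  pts <- .voxel_center_points(v)
  colSums(pts * as.double(w)) / s
}

#' Affine initial alignment by mutual information
#'
#' Optimizes a full 12-parameter affine transform (centered
#' parameterization), maximizing mutual information over a fixed
#' (jittered, seeded) sample set: BFGS capture on the coarsest pyramid
#' level from a center-of-mass translation, then a warm-started polish at
#' full resolution. Samples are drawn from the whole fixed domain —
#' restricting them to a body mask makes the estimator reward mapping
#' body-edge samples into background (a histogram artifact), which biases
#' global scaling. The returned affine is never worse than the identity
#' in dense-mode MI on the coarsest level.
#'
#' @param fixed,moving `mmdir_volume` objects.
#' @param cfg an [registration_config()].
#' @return An `mmdir_affine`.
#' @export
register_affine <- function(fixed, moving, cfg = registration_config()) {
  pf <- gaussian_pyramid(fixed, cfg$levels, cfg$sigmas, cfg$factors)
  pm <- gaussian_pyramid(moving, cfg$levels, cfg$sigmas, cfg$factors)
  fc <- pf[[1]]; mc <- pm[[1]]
  ctr <- fc$origin + (dim(fc$data) - 1) * fc$spacing / 2
  ext <- max(dim(fc$data) * fc$spacing)
  t0 <- .center_of_mass(mc) - .center_of_mass(fc)

  par_to_affine <- function(p) {
    M <- diag(3) + base::matrix(p[1:9], 3, 3)
    affine_transform(M, as.double(p[10:12]) + ctr - M %*% ctr)
  }
  affine_to_par <- function(a) {
    c(as.double(a$matrix - diag(3)),
      as.double(a$translation - ctr + a$matrix %*% ctr))
  }

  sample_level <- function(fl, n) {
    cand <- seq_len(length(fl$data)) - 1L
    set.seed(cfg$seed)
    take <- sample(length(cand), min(n, length(cand)))
    pts <- .voxel_center_points(fl, cand[take])
    # jitter off the voxel lattice: sampling exactly at voxel centers lets
    # interpolation blur beat against the grid and bias the estimator
    pts + sweep(base::matrix(runif(length(pts), -0.5, 0.5), ncol = 3), 2,
                fl$spacing, "*")
  }

  optimize_level <- function(fl, ml, p_init, n_samples) {
    micfg <- cfg$mi
    micfg$fixed_range <- .intensity_range(fl, micfg$range_quantiles)
    micfg$moving_range <- .intensity_range(ml, micfg$range_quantiles)
    pts <- sample_level(fl, n_samples)
    obj <- function(p) {
      aff <- diag(3) + base::matrix(p[1:9], 3, 3)
      if (abs(det(aff)) < 1e-6)
        return(list(value = 1e6, grad = rep(0, 12)))
      tr <- par_to_affine(p)
      y <- apply_transform_points(tr, pts)
      r <- .mi_at_points(pts, y, fl, ml, micfg)
      xc <- sweep(pts, 2, ctr)
      gP <- crossprod(r$dcdpos, xc)        # dC/dM[i,j]
      list(value = r$value, grad = c(as.double(gP), colSums(r$dcdpos)))
    }
    tryCatch(
      optim(p_init, fn = function(p) obj(p)$value,
            gr = function(p) obj(p)$grad, method = "BFGS",
            control = list(maxit = 200, reltol = 1e-10,
                           parscale = c(rep(2 / ext, 9), rep(1, 3))))$par,
      error = function(e) NULL)
  }

  # coarse capture, then a warm-started polish at full resolution with a
  # larger sample set (the coarsest level alone cannot resolve
  # millimetre-level scale changes)
  cands <- list(affine_transform(), par_to_affine(c(rep(0, 9), t0)))
  p1 <- optimize_level(fc, mc, c(rep(0, 9), t0), cfg$affine_samples)
  if (!is.null(p1)) {
    cands <- c(cands, list(par_to_affine(p1)))
    p2 <- optimize_level(pf[[cfg$levels]], pm[[cfg$levels]], p1,
                         4L * cfg$affine_samples)
    if (!is.null(p2)) cands <- c(cands, list(par_to_affine(p2)))
  }
  # pick the candidate by deterministic dense-mode MI at full resolution;
  # the identity is always among the candidates, so the result is never
  # worse than it in that measure
  ff <- pf[[cfg$levels]]; mf <- pm[[cfg$levels]]
  micfg <- cfg$mi
  micfg$fixed_range <- .intensity_range(ff, micfg$range_quantiles)
  micfg$moving_range <- .intensity_range(mf, micfg$range_quantiles)
  vals <- vapply(cands, function(a)
    tryCatch(mutual_information(a, ff, mf, micfg, mode = "dense")$value,
             error = function(e) Inf), 0)
  cands[[which.min(vals)]]
}

# MI value + position-derivatives at explicit (fixed point, mapped point)
# pairs; shared by the affine stage, which differentiates with respect to
# affine parameters rather than B-spline coefficients.
.mi_at_points <- function(pts, y, fixed, moving, micfg) {
  nb <- micfg$n_bins
  fv <- .trilinear_vol(fixed, pts)
  mv <- .trilinear_vol(moving, y, want_grad = TRUE)
  valid <- fv$inside & mv$inside
  if (sum(valid) < nb) stop("no overlap after initialization")
  fr <- micfg$fixed_range; mr <- micfg$moving_range
  if (diff(fr) <= 0 || diff(mr) <= 0)
    return(list(value = 0, dcdpos = base::matrix(0, nrow(pts), 3)))
  r <- .mi_parzen_core(fv$value[valid], mv$value[valid], fr, mr, nb,
                       want_grad = TRUE)
  dcdm <- double(nrow(pts))
  dcdm[valid] <- r$dcdm
  list(value = r$value, dcdpos = mv$grad * dcdm)
}

# Fused per-iteration objective for the B-spline stage: evaluates the
# transform and accumulates the coefficient gradient ONCE over the
# concatenated sample points of all active metrics, using the same metric
# cores as the public cost functions (a unit test pins the equivalence).
# caches: list(mi = list(pts, f), kappa = list(pts, A), pairs)
.fused_objective <- function(trc, w, caches, micfg, moving, roi_moving) {
  sw <- sum(w)
  pts_list <- list()
  if (!is.null(caches$mi)) pts_list$mi <- caches$mi$pts
  if (!is.null(caches$kappa)) pts_list$kappa <- caches$kappa$pts
  if (!is.null(caches$pairs)) pts_list$fid <- caches$pairs$fixed
  all_pts <- do.call(rbind, pts_list)
  y <- apply_transform_points(trc, all_pts)
  ns <- vapply(pts_list, nrow, 1L)
  ends <- cumsum(ns); starts <- ends - ns + 1L
  dcdpos <- base::matrix(0, nrow(all_pts), 3)
  value <- 0
  if (!is.null(caches$mi)) {
    i <- starts[["mi"]]:ends[["mi"]]
    mv <- .trilinear_vol(moving, y[i, , drop = FALSE], want_grad = TRUE)
    valid <- mv$inside
    if (sum(valid) < micfg$n_bins) stop("insufficient overlap")
    r <- .mi_parzen_core(caches$mi$f[valid], mv$value[valid],
                         micfg$fixed_range, micfg$moving_range,
                         micfg$n_bins, want_grad = TRUE)
    dcdm <- double(length(i))
    dcdm[valid] <- r$dcdm
    dcdpos[i, ] <- mv$grad * (dcdm * (w[["intensity"]] / sw))
    value <- value + w[["intensity"]] * r$value
  }
  if (!is.null(caches$kappa)) {
    i <- starts[["kappa"]]:ends[["kappa"]]
    mv <- .trilinear_vol(roi_moving, y[i, , drop = FALSE],
                         want_grad = TRUE, fill = 0)
    r <- .kappa_core(caches$kappa$A, mv$value, want_grad = TRUE)
    dcdpos[i, ] <- mv$grad * (r$dcdB * (w[["region"]] / sw))
    value <- value + w[["region"]] * r$value
  }
  if (!is.null(caches$pairs)) {
    i <- starts[["fid"]]:ends[["fid"]]
    diff <- caches$pairs$moving - y[i, , drop = FALSE]
    d <- sqrt(rowSums(diff^2))
    scale <- ifelse(d > 0, 1 / (length(d) * d), 0)
    dcdpos[i, ] <- -diff * scale * (w[["fiducial"]] / sw)
    value <- value + w[["fiducial"]] * mean(d)
  }
  grad <- .chain_to_mu(trc, all_pts, dcdpos)
  list(value = value / sw, gradient = grad)
}

#' Resample a volume onto a fixed grid through a transform
#'
#' @param v the moving `mmdir_volume`.
#' @param geometry target grid (`mmdir_volume`/`mmdir_mask`).
#' @param transform transform mapping target world to `v` world
#'   coordinates; `NULL` for identity.
#' @param fill intensity for points mapping outside `v` (default:
#'   `min(v$data)`).
#' @return An `mmdir_volume` on the target grid.
#' @export
resample_volume <- function(v, geometry, transform = NULL, fill = NULL) {
  if (is.null(fill)) fill <- min(v$data)
  pts <- .voxel_center_points(geometry)
  if (!is.null(transform)) pts <- apply_transform_points(transform, pts)
  vals <- .trilinear_vol(v, pts, fill = fill)$value
  volume(array(vals, dim(geometry$data)), geometry$spacing, geometry$origin)
}

# Deterministic (dense-mode) combined cost used for safeguarding and final
# reporting: full-support region term, dense-histogram intensity term.
.dense_combined <- function(transform, inputs, cfg, micfg,
                            mi_samples = NULL) {
  combined_cost(transform, inputs, weights = cfg$weights, cfg = micfg,
                gradient = FALSE, mi_mode = "dense",
                mi_samples = mi_samples, dilate_mm = cfg$dilate_mm)
}

#' Multi-metric deformable registration
#'
#' The full pipeline: affine initialization (mutual information only),
#' then, per Gaussian-pyramid level, a cubic B-spline deformation optimized
#' by stochastic gradient descent on the weighted combination of the
#' fiducial, region and intensity metrics, with exact dyadic control-grid
#' refinement between levels. Each level is safeguarded: if the stochastic
#' optimization ends with a worse deterministic (dense-mode) cost than it
#' started with, the level's starting coefficients are kept, so the
#' dense-mode cost never increases across a level.
#'
#' @param fixed,moving `mmdir_volume` objects (fixed = planning/post-op CT,
#'   moving = pre-op CT).
#' @param cfg an [registration_config()].
#' @param pairs optional `mmdir_points` fiducial pairs (world mm), required
#'   when the fiducial weight is nonzero.
#' @param roi_fixed,roi_moving optional `mmdir_mask` region pair, required
#'   when the region weight is nonzero.
#' @param fixed_mask optional body mask on the fixed grid restricting
#'   intensity sampling.
#' @param affine optional precomputed `mmdir_affine` initialization; the
#'   affine stage is intensity-only, so a method comparison can share one
#'   affine across its weight variants.
#' @return An object of class `mmdir_registration`: list with `transform`
#'   (an `mmdir_composite`), `affine`, `levels` (per-level traces and
#'   dense-mode start/end costs), `final_metrics` (deterministic
#'   per-metric values at the solution), `config`, `seed`.
#' @export
register_multimetric <- function(fixed, moving, cfg = registration_config(),
                                 pairs = NULL, roi_fixed = NULL,
                                 roi_moving = NULL, fixed_mask = NULL,
                                 affine = NULL) {
  w <- cfg$weights
  if (w["fiducial"] > 0 && is.null(pairs))
    stop("fiducial metric requires 'pairs'")
  if (w["region"] > 0 && (is.null(roi_fixed) || is.null(roi_moving)))
    stop("region metric requires 'roi_fixed' and 'roi_moving'")

  if (is.null(affine)) {
    affine <- if (cfg$do_affine) register_affine(fixed, moving, cfg)
    else affine_transform()
  } else stopifnot(inherits(affine, "mmdir_affine"))

  pyr_f <- gaussian_pyramid(fixed, cfg$levels, cfg$sigmas, cfg$factors)
  pyr_m <- gaussian_pyramid(moving, cfg$levels, cfg$sigmas, cfg$factors)
  schedule <- .grid_schedule(cfg, fixed)

  # region-term support (full resolution, fixed across levels)
  ksup_pts <- NULL; ksup_A <- NULL
  if (w["region"] > 0) {
    idx <- .kappa_support(roi_fixed, cfg$dilate_mm)
    ksup_pts <- .voxel_center_points(roi_fixed, idx)
    ksup_A <- as.double(roi_fixed$data[idx + 1L])
  }

  bsp <- NULL
  level_info <- vector("list", cfg$levels)
  for (lev in seq_len(cfg$levels)) {
    fl <- pyr_f[[lev]]; ml <- pyr_m[[lev]]
    micfg <- cfg$mi
    micfg$fixed_range <- .intensity_range(fl, micfg$range_quantiles)
    micfg$moving_range <- .intensity_range(ml, micfg$range_quantiles)
    bsp <- if (is.null(bsp)) bspline_grid_for(fixed, schedule[lev])
           else refine_bspline(bsp)
    tr <- composite_transform(affine, bsp)
    ncoef <- length(bsp$coefficients)

    cand <- if (!is.null(fixed_mask)) {
      mlv <- .trilinear_vol(fixed_mask, .voxel_center_points(fl))$value
      which(mlv >= 0.5) - 1L
    } else seq_len(length(fl$data)) - 1L
    if (length(cand) < cfg$mi$n_bins) cand <- seq_len(length(fl$data)) - 1L

    inputs_l <- list(pairs = pairs, roi_fixed = roi_fixed,
                     roi_moving = roi_moving, fixed = fl, moving = ml)
    # deterministic dense-evaluation points (strided when very large)
    dcand <- cand
    if (length(dcand) > 60000L)
      dcand <- dcand[seq(1L, length(dcand),
                         by = ceiling(length(dcand) / 60000))]
    dense_pts <- .voxel_center_points(fl, dcand)
    fl_vals <- as.double(fl$data)

    cost_fn <- function(par, it) {
      trc <- .with_coefficients(tr, par)
      it_seed <- (cfg$seed %% 100000L) * 17L + lev * 1009L + it
      set.seed(it_seed)
      mi_take <- cand[sample(length(cand),
                             min(micfg$n_samples, length(cand)))]
      caches <- list(mi = list(pts = .voxel_center_points(fl, mi_take),
                               f = fl_vals[mi_take + 1L]))
      if (w[["region"]] > 0) {
        ks <- sample(nrow(ksup_pts), min(cfg$kappa_samples, nrow(ksup_pts)))
        caches$kappa <- list(pts = ksup_pts[ks, , drop = FALSE],
                             A = ksup_A[ks])
      }
      if (w[["fiducial"]] > 0) caches$pairs <- pairs
      if (w[["intensity"]] == 0) caches$mi <- NULL
      .fused_objective(trc, w, caches, micfg, ml, roi_moving)
    }

    start_cost <- .dense_combined(tr, inputs_l, cfg, micfg,
                                  mi_samples = dense_pts)$value
    opt <- sgd_minimize(cost_fn, as.double(bsp$coefficients),
                        max_iter = cfg$max_iter, A = cfg$sgd_A,
                        alpha = cfg$sgd_alpha, step0 = cfg$step0,
                        tol = cfg$tol)
    cand_tr <- .with_coefficients(tr, opt$par)
    end_cost <- .dense_combined(cand_tr, inputs_l, cfg, micfg,
                                mi_samples = dense_pts)$value
    if (is.finite(end_cost) && end_cost <= start_cost) {
      bsp <- .bspline_part(cand_tr)
    } # else keep level-start coefficients (safeguard)
    level_info[[lev]] <- list(iterations = opt$iterations,
                              trace = opt$trace,
                              dense_start = start_cost,
                              dense_end = min(start_cost, end_cost,
                                              na.rm = TRUE))
  }

  final_tr <- composite_transform(affine, bsp)
  micfg <- cfg$mi
  micfg$fixed_range <- .intensity_range(fixed, micfg$range_quantiles)
  micfg$moving_range <- .intensity_range(moving, micfg$range_quantiles)
  final <- .dense_combined(final_tr,
                           list(pairs = pairs, roi_fixed = roi_fixed,
                                roi_moving = roi_moving, fixed = fixed,
                                moving = moving, fixed_mask = fixed_mask),
                           cfg, micfg)
  structure(list(transform = final_tr, affine = affine,
                 levels = level_info, final_metrics = final$components,
                 final_cost = final$value, config = cfg, seed = cfg$seed),
            class = "mmdir_registration")
}

#' @export
print.mmdir_registration <- function(x, ...) {
  cat("<mmdir_registration>\n")
  for (lev in seq_along(x$levels)) {
    li <- x$levels[[lev]]
    cat(sprintf("  level %d: %d iterations, dense cost %.6g -> %.6g\n",
                lev, li$iterations, li$dense_start, li$dense_end))
  }
  fm <- x$final_metrics
  cat("  final metrics:",
      paste(sprintf("%s = %.4g", names(fm), fm)[!is.na(fm)],
            collapse = ", "), "\n")
  invisible(x)
}
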