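# Synthetic resection phantom: paired "pre-operative" / "post-operative"
# CT-like volumes with a known smooth ground-truth deformation and
# surgically induced non-correspondence (tumor replaced by a seroma-like
# cavity plus bright clips).
#
# The phantom is geometric-primitive based, not anatomy-realistic; it
# carries exactly the features the metrics exploit: glandular texture for
# mutual information and corner detection, a gland blob for the region
# term, rib-like rods, and a skin boundary with a nipple-like bump for the
# three landmark groups. The post-operative volume is produced by warping
# FIRST and resecting SECOND, so the resected region genuinely lacks a
# correspondence in the pre-operative image.

#' Phantom settings
#'
#' Defaults describe a breast-like soft-tissue volume on a 96 x 96 x 48
#' grid at 1.5 x 1.5 x 3 mm. Intensities are CT-like (HU-flavored
#' arbitrary units). The deformation coefficient amplitude (25 mm,
#' yielding realized landmark displacements with a median around 6-8 mm)
#' is chosen so that pre-registration landmark error matches the scale of
#' soft tissue/boundary misalignment reported for clinical
#' pre/post-operative breast CT pairs (where intensity-only registration
#' leaves soft-tissue errors near 8 mm).
#'
#' @param shape grid size, voxels.
#' @param spacing voxel spacing, mm.
#' @param levels named intensity levels (background, fat, muscle, gland,
#'   rib, nipple, tumor, seroma, clip).
#' @param tumor_center,tumor_radius tumor sphere, world mm (center `NULL`
#'   = default location inside the gland).
#' @param amplitude B-spline coefficient amplitude of the ground-truth
#'   deformation, mm.
#' @param control_spacing control spacing of the ground-truth deformation,
#'   mm.
#' @param taper_mm edge taper width of the deformation.
#' @param n_soft,n_rigid,n_boundary landmarks per tissue group (defaults
#'   20/5/5, thirty pairs in total).
#' @param n_clips surgical clips marking the cavity boundary (>= 5).
#' @param cavity_margin_mm cavity = tumor dilated by this margin; the
#'   default reproduces the clinically reported tumor-bed to tumor volume
#'   ratio of roughly nine.
#' @param noise_sd additive Gaussian noise, intensity units.
#' @param texture_sd weak smooth background texture inside the body.
#' @param texture_sigma background-texture correlation length, voxels.
#' @param n_speckles,speckle_radius sparse bright glandular
#'   strands/spots inside the gland region (count; radius in mm). These
#'   are the distinctive soft-tissue features: corner detection and
#'   patch correlation lock onto them, while randomly sampled
#'   intensity metrics only graze them — the phantom's rendition of why
#'   intensity-only registration underperforms on soft tissue.
#' @param collapse_mm peak of the radial tissue collapse toward the
#'   resection bed that is added to the ground-truth deformation when
#'   `resection` is on (the "tumor bed creation" component); its intensity
#'   evidence is erased by the seroma fill, which is precisely what makes
#'   the resection case hard for intensity-only registration.
#' @param resection simulate the resection on the post-operative volume.
#' @param seed integer seed; the whole case is deterministic given it.
#' @return An object of class `mmdir_phantom_config`.
#' @export
phantom_config <- function(shape = c(96, 96, 48), spacing = c(1.5, 1.5, 3),
                           levels = c(background = -1000, fat = -100,
                                      muscle = 30, gland = 40, rib = 700,
                                      nipple = 20, tumor = 120,
                                      seroma = 25, clip = 2500),
                           tumor_center = NULL, tumor_radius = 9,
                           amplitude = 25, control_spacing = 24,
                           taper_mm = 25, n_soft = 20, n_rigid = 5,
                           n_boundary = 5, n_clips = 6,
                           cavity_margin_mm = 10, noise_sd = 10,
                           texture_sd = 6, texture_sigma = 2.5,
                           n_speckles = 250, speckle_radius = 3,
                           collapse_mm = 6, resection = TRUE, seed = 1) {
  shape <- as.integer(shape); spacing <- as.double(spacing)
  if (length(shape) != 3L || any(shape < 16L)) stop("shape too small")
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (n_clips < 5L)
    stop("at least five surgical clips are required")
  if (amplitude < 0 || tumor_radius <= 0) stop("invalid phantom settings")
  structure(list(shape = shape, spacing = spacing, levels = levels,
                 tumor_center = tumor_center, tumor_radius = tumor_radius,
                 amplitude = amplitude, control_spacing = control_spacing,
                 taper_mm = taper_mm, n_soft = as.integer(n_soft),
                 n_rigid = as.integer(n_rigid),
                 n_boundary = as.integer(n_boundary),
                 n_clips = as.integer(n_clips),
                 cavity_margin_mm = cavity_margin_mm, noise_sd = noise_sd,
                 texture_sd = texture_sd, texture_sigma = texture_sigma,
                 n_speckles = as.integer(n_speckles),
                 speckle_radius = speckle_radius,
                 collapse_mm = collapse_mm, resection = isTRUE(resection),
                 seed = as.integer(seed)),
            class = "mmdir_phantom_config")
}

#' Random smooth B-spline deformation with bounded amplitude
#'
#' Coefficients are drawn i.i.d. uniform in `[-amplitude, amplitude]` per
#' component (vector norms clipped to `amplitude`), then tapered smoothly
#' to zero within `taper_mm` of the domain faces, so the displacement
#' vanishes at the volume edge. By the cubic B-spline partition of unity
#' the displacement magnitude never exceeds `amplitude` anywhere.
#'
#' @param geometry an `mmdir_volume`/`mmdir_mask` defining the domain.
#' @param control_spacing control-point spacing, mm.
#' @param amplitude coefficient amplitude, mm (>= 0).
#' @param seed RNG seed.
#' @param taper_mm edge taper width, mm.
#' @return An `mmdir_bspline` mapping the domain onto itself.
#' @export
random_smooth_deformation <- function(geometry, control_spacing, amplitude,
                                      seed = 1, taper_mm = 25) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  bsp <- bspline_grid_for(geometry, control_spacing)
  if (amplitude == 0) return(bsp)
  set.seed(seed)
  nd <- bsp$grid_dim
  n <- prod(nd)
  cf <- base::matrix(runif(3 * n, -amplitude, amplitude), n, 3)
  nr <- sqrt(rowSums(cf^2))
  over <- nr > amplitude
  cf[over, ] <- cf[over, ] * (amplitude / nr[over])
  # smooth taper to zero at the domain faces
  dom <- .domain_of(geometry)
  smoothstep <- function(t) { t <- pmin(pmax(t, 0), 1); t * t * (3 - 2 * t) }
  wts <- rep(1, n)
  node_pos <- as.matrix(expand.grid(
    x = bsp$grid_origin[1] + (seq_len(nd[1]) - 1) * bsp$grid_spacing[1],
    y = bsp$grid_origin[2] + (seq_len(nd[2]) - 1) * bsp$grid_spacing[2],
    z = bsp$grid_origin[3] + (seq_len(nd[3]) - 1) * bsp$grid_spacing[3]))
  for (ax in 1:3) {
    dlo <- (node_pos[, ax] - dom$lo[ax]) / taper_mm
    dhi <- (dom$hi[ax] - node_pos[, ax]) / taper_mm
    wts <- wts * smoothstep(dlo) * smoothstep(dhi)
  }
  cf <- cf * wts
  bsp$coefficients <- array(as.double(cf), c(nd, 3L))
  bsp
}

# Ellipsoid / sphere / slab helpers over world-coordinate arrays.
.phantom_coords <- function(cfg) {
  tmpl <- volume(array(0, cfg$shape), cfg$spacing)
  d <- cfg$shape
  x <- (seq_len(d[1]) - 1) * cfg$spacing[1]
  y <- (seq_len(d[2]) - 1) * cfg$spacing[2]
  z <- (seq_len(d[3]) - 1) * cfg$spacing[3]
  list(tmpl = tmpl,
       X = array(rep(x, times = d[2] * d[3]), d),
       Y = array(rep(rep(y, each = d[1]), times = d[3]), d),
       Z = array(rep(z, each = d[1] * d[2]), d))
}

.ellipsoid <- function(co, center, semi) {
  ((co$X - center[1]) / semi[1])^2 + ((co$Y - center[2]) / semi[2])^2 +
    ((co$Z - center[3]) / semi[3])^2 <= 1
}

# Anatomy masks and the clean (noiseless) pre-operative volume.
.phantom_anatomy <- function(cfg) {
  co <- .phantom_coords(cfg)
  d <- cfg$shape
  ext <- (d - 1) * cfg$spacing
  cx <- ext[1] / 2; cz <- ext[3] / 2
  lv <- cfg$levels

  slab <- co$Y <= 22
  breast <- .ellipsoid(co, c(cx, 22, cz), c(0.39 * ext[1], 75, 0.39 * ext[3])) &
    co$Y > 22
  nipple <- .ellipsoid(co, c(cx, 96, cz), c(5, 5, 5))
  ribs <- array(FALSE, d)
  for (zr in seq(15, ext[3] - 10, by = 28))
    ribs <- ribs | (((co$Y - 12)^2 + (co$Z - zr)^2) <= 16 & slab)
  sternum <- (((co$X - cx)^2 + (co$Y - 14)^2) <= 25) & slab
  gland <- .ellipsoid(co, c(cx, 56, cz), c(0.3 * ext[1], 32, 0.3 * ext[3]))
  tc <- if (is.null(cfg$tumor_center)) c(cx + 14, 64, cz + 10) else
    cfg$tumor_center
  tumor <- .ellipsoid(co, tc, rep(cfg$tumor_radius, 3))
  if (!any(tumor)) stop("tumor sphere misses the grid")
  if (any(tumor & !gland))
    stop("tumor must lie strictly inside the gland region")
  body <- slab | breast | nipple

  arr <- array(lv[["background"]], d)
  arr[body] <- lv[["fat"]]
  arr[slab] <- lv[["muscle"]]
  arr[nipple & !breast] <- lv[["nipple"]]
  arr[ribs | sternum] <- lv[["rib"]]

  # sparse fibroglandular strands: the gland "region" is mostly fat with
  # isolated bright spots; these are the only distinctive soft-tissue
  # features, as on real non-contrast CT
  gidx <- which(gland & !tumor)
  ns <- min(cfg$n_speckles, length(gidx))
  centers <- arrayInd(sample(gidx, ns), d)
  # heterogeneous spots: random size and contrast, so a correlation patch
  # can tell neighboring spots apart (an intensity histogram cannot)
  radii <- runif(ns, 0.6, 1.5) * cfg$speckle_radius
  gains <- runif(ns, 0.7, 1.3)
  strand <- array(FALSE, d)
  sfield <- array(0, d)
  rvmax <- pmax(1L, ceiling(max(radii) / cfg$spacing))
  off <- as.matrix(expand.grid(-rvmax[1]:rvmax[1], -rvmax[2]:rvmax[2],
                               -rvmax[3]:rvmax[3]))
  off_mm2 <- rowSums(sweep(off, 2, cfg$spacing, "*")^2)
  for (i in seq_len(ns)) {
    sel <- off_mm2 <= radii[i]^2
    vox <- sweep(off[sel, , drop = FALSE], 2, centers[i, ], "+")
    ok <- vox[, 1] >= 1 & vox[, 1] <= d[1] & vox[, 2] >= 1 &
      vox[, 2] <= d[2] & vox[, 3] >= 1 & vox[, 3] <= d[3]
    vox <- vox[ok, , drop = FALSE]
    strand[vox] <- TRUE
    sfield[vox] <- pmax(sfield[vox], gains[i])
  }
  strand <- strand & gland
  sfield[!gland] <- 0
  # soften strand edges so interpolation and matching behave smoothly
  sfield <- .smooth_gaussian(sfield, 0.8)
  arr <- arr + (lv[["gland"]] - lv[["fat"]]) * sfield *
    (body & !slab & !(ribs | sternum))
  # weak smooth background texture
  tex <- .smooth_gaussian(array(rnorm(prod(d)), d), cfg$texture_sigma)
  tex <- tex / sd(tex)
  softish <- body & !(ribs | sternum)
  arr[softish] <- arr[softish] + cfg$texture_sd * tex[softish]
  arr[tumor] <- lv[["tumor"]]

  list(clean = volume(arr, cfg$spacing), co = co,
       masks = list(body = body, gland = gland, tumor = tumor,
                    rigid = ribs | sternum, slab = slab, strand = strand),
       nipple_center = c(cx, 96, cz), tumor_center = tc)
}

#' Simulate a lumpectomy on a (post-operative) volume
#'
#' Replaces the cavity region — the supplied tumor mask dilated by the
#' configured shrink/swell margin — with a seroma-like intensity plus
#' noise, and inserts `n_clips` single-voxel bright clips spread over the
#' cavity boundary (farthest-point sampling). Voxels outside cavity and
#' clips are returned bit-exactly unchanged.
#'
#' @param v the warped post-operative `mmdir_volume`.
#' @param tumor nonempty `mmdir_mask` of the (mapped) tumor on `v`'s grid.
#' @param cfg an [phantom_config()] (levels, margins, clip count, noise).
#' @param seed RNG seed for cavity noise and clip placement.
#' @return An `mmdir_volume` with attributes `cavity` and `clips`
#'   (`mmdir_mask` objects).
#' @export
simulate_resection <- function(v, tumor, cfg = phantom_config(),
                               seed = NULL) {
  if (!inherits(tumor, "mmdir_mask") || !any(tumor$data))
    stop("tumor mask is empty")
  if (!same_geometry(v, tumor)) .stop_geometry("volume and tumor mask")
  if (!is.null(seed)) set.seed(seed)
  cavity <- expand_margin(tumor, cfg$cavity_margin_mm)
  arr <- v$data
  idx <- which(cavity$data)
  arr[idx] <- cfg$levels[["seroma"]] +
    rnorm(length(idx), 0, cfg$noise_sd / 2)
  bnd <- which(.boundary_mask(cavity))
  if (length(bnd) < cfg$n_clips)
    stop("cavity too small for the requested clip count")
  pts <- .voxel_center_points(v, bnd - 1L)
  sel <- integer(cfg$n_clips)
  sel[1] <- sample(length(bnd), 1)
  dmin <- sqrt(rowSums(sweep(pts, 2, pts[sel[1], ])^2))
  for (i in seq_len(cfg$n_clips)[-1]) {
    sel[i] <- which.max(dmin)
    dmin <- pmin(dmin, sqrt(rowSums(sweep(pts, 2, pts[sel[i], ])^2)))
  }
  clips <- array(FALSE, dim(v$data))
  clips[bnd[sel]] <- TRUE
  arr[bnd[sel]] <- cfg$levels[["clip"]]
  out <- volume(arr, v$spacing, v$origin)
  attr(out, "cavity") <- cavity
  attr(out, "clips") <- label_mask(clips, spacing = v$spacing,
                                   origin = v$origin)
  out
}

# Greedy landmark picker with a minimum pairwise separation.
.pick_landmarks <- function(pts, n, min_sep = 8) {
  if (nrow(pts) == 0 || n < 1) return(base::matrix(0, 0, 3))
  ord <- sample(nrow(pts))
  chosen <- integer(0)
  for (i in ord) {
    if (length(chosen) == 0) { chosen <- i; next }
    dmin <- min(sqrt(rowSums(sweep(pts[chosen, , drop = FALSE], 2,
                                   pts[i, ])^2)))
    if (dmin >= min_sep) chosen <- c(chosen, i)
    if (length(chosen) == n) break
  }
  pts[chosen, , drop = FALSE]
}

#' Generate a synthetic resection phantom case
#'
#' Builds the pre-operative volume (breast-like body with textured gland,
#' tumor, rib-like rods, nipple bump), samples a random smooth
#' ground-truth deformation, produces the post-operative volume by
#' resampling through it, optionally simulates the resection, and derives
#' every ground-truth artifact: grouped landmark pairs (exact under the
#' ground-truth transform), gland ROIs on both images, body masks, the
#' tumor mask and its mapped cavity ("tumor bed"), and a boost-CTV-style
#' expansion limited to 5 mm from the skin. Fully deterministic per seed.
#'
#' @param cfg an [phantom_config()].
#' @return An object of class `mmdir_phantom`: list with `moving`,
#'   `fixed`, `gt_transform` (fixed world to moving world),
#'   `landmarks`, `gland_fixed`, `gland_moving`, `tumor`, `tumor_bed`,
#'   `boost_ctv`, `body_fixed`, `body_moving`, `cavity_moving`, `config`.
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  set.seed(cfg$seed)
  an <- .phantom_anatomy(cfg)
  tmpl <- an$clean
  lv <- cfg$levels
  mk <- function(m) label_mask(m, spacing = cfg$spacing)

  gt <- random_smooth_deformation(tmpl, cfg$control_spacing, cfg$amplitude,
                                  seed = cfg$seed + 1L,
                                  taper_mm = cfg$taper_mm)
  if (cfg$resection && cfg$collapse_mm > 0) {
    # surgical collapse: post-operative tissue near the bed corresponds to
    # pre-operative tissue displaced radially outward, peaking at the
    # cavity boundary; refine the grid so the localized bump is
    # representable
    gt <- refine_bspline(gt)
    nd <- gt$grid_dim
    node_pos <- as.matrix(expand.grid(
      gt$grid_origin[1] + (seq_len(nd[1]) - 1) * gt$grid_spacing[1],
      gt$grid_origin[2] + (seq_len(nd[2]) - 1) * gt$grid_spacing[2],
      gt$grid_origin[3] + (seq_len(nd[3]) - 1) * gt$grid_spacing[3]))
    rvec <- sweep(node_pos, 2, an$tumor_center)
    r <- sqrt(rowSums(rvec^2))
    sig <- cfg$tumor_radius + cfg$cavity_margin_mm
    gshape <- (r / sig) * exp(0.5 * (1 - (r / sig)^2))  # peak 1 at r = sig
    disp <- rvec / pmax(r, 1e-9) * (cfg$collapse_mm * gshape)
    gt$coefficients <- gt$coefficients + array(disp, c(nd, 3L))
  }
  # warp every voxel center once; reuse for the volume and all masks
  ywarp <- apply_transform_points(gt, .voxel_center_points(tmpl))
  warp_vals <- function(v, fill) {
    array(.trilinear_vol(v, ywarp, fill = fill)$value, cfg$shape)
  }
  warp_mask <- function(m) {
    label_mask(warp_vals(m, 0) >= 0.5, spacing = cfg$spacing)
  }
  fixed_clean <- volume(warp_vals(an$clean, lv[["background"]]),
                        cfg$spacing)

  body_m <- mk(an$masks$body)
  gland_m <- mk(an$masks$gland)
  tumor_m <- mk(an$masks$tumor)
  rigid_m <- mk(an$masks$rigid)
  strand_m <- mk(an$masks$strand)
  body_f <- warp_mask(body_m)
  gland_f <- warp_mask(gland_m)
  rigid_f <- warp_mask(rigid_m)
  tumor_f <- warp_mask(tumor_m)
  strand_f <- warp_mask(strand_m)
  cavity_m <- expand_margin(tumor_m, cfg$cavity_margin_mm)

  if (cfg$resection) {
    fx <- simulate_resection(fixed_clean, tumor_f, cfg,
                             seed = cfg$seed + 2L)
    cavity_f <- attr(fx, "cavity")
    clips_f <- attr(fx, "clips")
  } else {
    fx <- fixed_clean
    cavity_f <- warp_mask(cavity_m)
    clips_f <- NULL
  }

  set.seed(cfg$seed + 3L)
  if (cfg$noise_sd > 0) {
    moving <- volume(an$clean$data +
                       rnorm(length(an$clean$data), 0, cfg$noise_sd),
                     cfg$spacing)
    fixed <- volume(fx$data + rnorm(length(fx$data), 0, cfg$noise_sd),
                    cfg$spacing)
  } else {
    moving <- an$clean; fixed <- volume(fx$data, cfg$spacing)
  }

  # unaffected-gland ROIs: gland minus the tumor/cavity neighborhood.
  # The fixed-side contour is exactly the warped image of the moving-side
  # one, as a carefully drawn pair of post/pre-operative contours of the
  # same structure would be; the moving-side exclusion (tumor plus
  # cavity margin plus 4 mm) already keeps the warped contour clear of
  # the resection bed.
  excl_m <- expand_margin(tumor_m, cfg$cavity_margin_mm + 4)
  gland_roi_m <- mk(gland_m$data & !excl_m$data)
  gland_roi_f <- warp_mask(gland_roi_m)

  # landmark groups: pick fixed-grid voxel centers via the propagated
  # masks; pairs are exact under the ground-truth transform
  set.seed(cfg$seed + 4L)
  # soft-tissue landmarks live on the glandular strands — the detectable
  # structures an automatic detector (or an oncologist) would pick
  soft_f <- strand_f$data & gland_f$data & !warp_mask(excl_m)$data
  bnd_f <- .boundary_mask(body_f)
  pick_group <- function(mask_arr, n, near = NULL, radius = Inf) {
    idx <- which(mask_arr) - 1L
    if (length(idx) == 0) stop("no candidate landmarks in a tissue group")
    pf <- .voxel_center_points(tmpl, idx)
    if (!is.null(near)) {
      pm <- apply_transform_points(gt, pf)
      keep <- sqrt(rowSums(sweep(pm, 2, near)^2)) <= radius
      pf <- pf[keep, , drop = FALSE]
    }
    .pick_landmarks(pf, n)
  }
  # soft-tissue points: unaffected gland within 50 mm of the tumor, the
  # region where registration quality matters most clinically
  pf_soft <- pick_group(soft_f, cfg$n_soft, near = an$tumor_center,
                        radius = 50)
  pf_rigid <- pick_group(rigid_f$data, cfg$n_rigid)
  pf_bnd <- pick_group(bnd_f, cfg$n_boundary, near = an$nipple_center,
                       radius = 35)
  pf <- rbind(pf_soft, pf_rigid, pf_bnd)
  groups <- c(rep("soft_tissue", nrow(pf_soft)),
              rep("rigid", nrow(pf_rigid)),
              rep("boundary", nrow(pf_bnd)))
  landmarks <- paired_points(pf, apply_transform_points(gt, pf), groups)

  tumor_bed <- cavity_f
  boost_ctv <- expand_margin(tumor_bed, 10,
                             limit = skin_limit_mask(body_f, 5))

  structure(list(moving = moving, fixed = fixed, gt_transform = gt,
                 landmarks = landmarks, gland_fixed = gland_roi_f,
                 gland_moving = gland_roi_m, tumor = tumor_m,
                 tumor_bed = tumor_bed, boost_ctv = boost_ctv,
                 body_fixed = body_f, body_moving = body_m,
                 cavity_moving = cavity_m, clips = clips_f,
                 config = cfg),
            class = "mmdir_phantom")
}

#' @export
print.mmdir_phantom <- function(x, ...) {
  cat(sprintf(
    "<mmdir_phantom> %s @ (%s) mm, %d landmark pairs, resection: %s\n",
    paste(x$config$shape, collapse = "x"),
    paste(format(x$config$spacing), collapse = ", "),
    nrow(x$landmarks$fixed),
    if (x$config$resection) "yes" else "no"))
  invisible(x)
}
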