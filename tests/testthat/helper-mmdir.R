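# Shared fixture builders. Everything is generated in code; no binary
# fixtures on disk.

# random intensity volume
rand_volume <- function(n = 16, seed = 1, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0), mean = 50, sd = 20) {
  n <- rep(n, length.out = 3)
  set.seed(seed)
  volume(array(rnorm(prod(n), mean, sd), n),
         spacing = spacing, origin = origin)
}

# spherical mask in voxel coordinates
sphere_mask <- function(dims, center, radius, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  g <- as.matrix(expand.grid(i = seq_len(dims[1]) - 1,
                             j = seq_len(dims[2]) - 1,
                             k = seq_len(dims[3]) - 1))
  w <- sweep(g, 2, spacing, "*")
  d <- sqrt(rowSums(sweep(w, 2, center * spacing)^2))
  label_mask(array(d <= radius, dims), spacing = spacing, origin = origin)
}

# random blob mask (nonempty, with interior): a few dilated random seeds
rand_mask <- function(dims, seed = 1, spacing = c(1, 1, 1), p = 0.02,
                      grow_mm = 1.5) {
  set.seed(seed)
  m <- array(runif(prod(dims)) < p, dims)
  if (!any(m)) m[ceiling(prod(dims) / 2)] <- TRUE
  mk <- label_mask(m, spacing = spacing)
  expand_margin(mk, grow_mm)
}

# random small B-spline transform (plus a non-lattice translation so
# interpolation gradients are evaluated at generic positions)
rand_bspline_transform <- function(vol, grid_mm = 5, amp = 1.5, seed = 1,
                                   shift = c(0.3, -0.2, 0.4)) {
  b <- bspline_grid_for(vol, grid_mm)
  set.seed(seed)
  b$coefficients[] <- runif(length(b$coefficients), -amp, amp)
  composite_transform(affine_transform(diag(3), shift), b)
}

# brute-force MI in bits from two already-binned integer vectors
oracle_mi_bits <- function(fb, mb, nb) {
  P <- matrix(0, nb, nb)
  for (i in seq_along(fb)) P[fb[i] + 1, mb[i] + 1] <- P[fb[i] + 1, mb[i] + 1] + 1
  P <- P / length(fb)
  pF <- rowSums(P); pM <- colSums(P)
  s <- 0
  for (f in 1:nb) for (m in 1:nb)
    if (P[f, m] > 0) s <- s + P[f, m] * log2(P[f, m] / (pF[f] * pM[m]))
  s
}

# intensity binning identical to the dense-mode contract
bin_hard <- function(vals, r, nb) {
  w <- diff(r) / nb
  pmin(pmax(floor((vals - r[1]) / w), 0), nb - 1)
}

# quick phantom at coarse spacing (same 144 mm world extent, 8x fewer
# voxels) for smoke tests
small_phantom_config <- function(seed = 1, ...) {
  phantom_config(shape = c(48, 48, 24), spacing = c(3, 3, 6), seed = seed,
                 ...)
}

# reduced-effort registration config for smoke tests (documented
# scale-down; the acceptance suite uses the defaults)
smoke_reg_config <- function(seed = 1, ...) {
  registration_config(max_iter = 60, affine_samples = 2000, seed = seed,
                      ...)
}
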