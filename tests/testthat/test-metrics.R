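# The three cost terms and their weighted combination.

test_that("fiducial cost matches its closed forms and a loop oracle", {
  p <- matrix(runif(30, 0, 10), 10, 3)
  expect_equal(fiducial_cost(identity_transform(),
                             paired_points(p, p))$value, 0)
  off <- sweep(p, 2, c(3, 4, 0), "+")
  expect_equal(fiducial_cost(identity_transform(),
                             paired_points(p, off))$value, 5)
  # random pairs under a random affine vs a direct per-pair loop
  set.seed(11)
  aff <- affine_transform(diag(3) + matrix(rnorm(9, 0, 0.05), 3),
                          rnorm(3))
  q <- matrix(runif(30, 0, 10), 10, 3)
  got <- fiducial_cost(aff, paired_points(p, q))$value
  want <- 0
  for (i in 1:10) {
    ti <- aff$matrix %*% p[i, ] + aff$translation
    want <- want + sqrt(sum((q[i, ] - ti)^2))
  }
  expect_equal(got, want / 10, tolerance = 1e-12)
  # invariant to pair order
  o <- sample(10)
  expect_equal(fiducial_cost(aff, paired_points(p[o, ], q[o, ]))$value, got)
  expect_error(fiducial_cost(identity_transform(), NULL),
               "no fiducial pairs")
})

test_that("kappa cost matches Eq-style arithmetic and is symmetric", {
  dims <- c(12, 12, 12)
  a <- sphere_mask(dims, c(6, 6, 6), 3)
  expect_equal(kappa_cost(identity_transform(), a, a)$value, 0)
  expect_equal(kappa_statistic(identity_transform(), a, a), 1)
  b <- sphere_mask(dims, c(2, 2, 2), 1.2)
  c2 <- sphere_mask(dims, c(9, 9, 9), 1.2)
  expect_equal(kappa_cost(identity_transform(), b, c2)$value, 1)
  # |A| = |B| = 4, overlap 2 -> KS = 0.5
  A <- array(FALSE, dims); B <- array(FALSE, dims)
  A[3:6, 3, 3] <- TRUE; B[5:8, 3, 3] <- TRUE
  Am <- label_mask(A, spacing = c(1, 1, 1))
  Bm <- label_mask(B, spacing = c(1, 1, 1))
  expect_equal(kappa_statistic(identity_transform(), Am, Bm), 0.5)
  expect_equal(kappa_cost(identity_transform(), Am, Bm)$value, 0.5)
  # symmetry of the hard statistic
  expect_equal(kappa_statistic(identity_transform(), Am, Bm),
               kappa_statistic(identity_transform(), Bm, Am))
  expect_error(kappa_cost(identity_transform(), Am,
                          label_mask(array(FALSE, dims))), "empty ROI")
})

test_that("dense MI reproduces closed forms and a double-sum oracle", {
  # two equiprobable levels, 2 bins -> 1 bit
  arr <- array(rep(c(0, 100), 32), c(4, 4, 4))
  v <- volume(arr)
  r <- mutual_information(identity_transform(), v, v, mi_config(n_bins = 2),
                          mode = "dense")
  expect_equal(r$mi, 1.0)
  # constant moving image -> degenerate marginal -> MI = 0
  r0 <- mutual_information(identity_transform(), v,
                           volume(array(5, c(4, 4, 4))),
                           mi_config(n_bins = 8), mode = "dense")
  expect_equal(r0$mi, 0)
  # random paired volumes vs explicit double-sum oracle
  for (seed in 1:5) {
    f <- rand_volume(8, seed = seed)
    m <- rand_volume(8, seed = seed + 50)
    nb <- 8
    cfg <- mi_config(n_bins = nb)
    got <- mutual_information(identity_transform(), f, m, cfg,
                              mode = "dense")$mi
    fr <- quantile(f$data, cfg$range_quantiles, names = FALSE)
    mr <- quantile(m$data, cfg$range_quantiles, names = FALSE)
    want <- oracle_mi_bits(bin_hard(as.vector(f$data), fr, nb),
                           bin_hard(as.vector(m$data), mr, nb), nb)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("MI(v, v) equals the entropy of the bin histogram", {
  v <- rand_volume(12, seed = 7)
  cfg <- mi_config(n_bins = 32)
  r <- mutual_information(identity_transform(), v, v, cfg, mode = "dense")
  fr <- quantile(v$data, cfg$range_quantiles, names = FALSE)
  p <- tabulate(bin_hard(as.vector(v$data), fr, 32) + 1L, 32)
  p <- p[p > 0] / length(v$data)
  expect_equal(r$mi, -sum(p * log2(p)), tolerance = 1e-9)
})

test_that("MI of independent volumes is near zero", {
  f <- rand_volume(48, seed = 1)
  m <- rand_volume(48, seed = 2)
  r <- mutual_information(identity_transform(), f, m, mi_config(),
                          mode = "dense")
  expect_gte(r$mi, 0)
  expect_lt(r$mi, 0.05)
})

test_that("MI errors on insufficient overlap", {
  f <- rand_volume(8, seed = 1)
  m <- rand_volume(8, seed = 2)
  far <- affine_transform(translation = c(1000, 0, 0))
  expect_error(mutual_information(far, f, m, mi_config(n_bins = 8)),
               "insufficient overlap")
})

test_that("combined cost weights components as a normalized sum", {
  # direct arithmetic of the weighted mean with the published weights
  w <- c(1, 1, 100); C <- c(2.0, 0.5, -1.2)
  expect_equal(sum(w * C) / sum(w), -1.151961, tolerance = 1e-6)

  f <- rand_volume(12, seed = 3)
  m <- rand_volume(12, seed = 4)
  roi_f <- sphere_mask(c(12, 12, 12), c(6, 6, 6), 3)
  roi_m <- sphere_mask(c(12, 12, 12), c(7, 6, 6), 3)
  set.seed(5)
  prs <- paired_points(matrix(runif(30, 2, 9), 10, 3),
                       matrix(runif(30, 2, 9), 10, 3))
  inputs <- list(pairs = prs, roi_fixed = roi_f, roi_moving = roi_m,
                 fixed = f, moving = m)
  tr <- rand_bspline_transform(f, seed = 6)
  # exactly one nonzero weight -> identical to that component
  single <- combined_cost(tr, inputs, metric_weights(1, 0, 0),
                          cfg = mi_config(n_bins = 8), mi_mode = "dense")
  expect_identical(single$value, fiducial_cost(tr, prs)$value)
  # random weights agree with a direct weighted mean of the components
  for (i in 1:20) {
    set.seed(100 + i)
    w <- runif(3, 0.01, 10)
    r <- combined_cost(tr, inputs, metric_weights(w[1], w[2], w[3]),
                       cfg = mi_config(n_bins = 8), mi_mode = "dense")
    expect_equal(r$value, sum(w * r$components) / sum(w),
                 tolerance = 1e-12)
  }
  expect_error(metric_weights(0, 0, 0), "positive")
  expect_error(combined_cost(tr, inputs[-1], metric_weights(1, 0, 0)),
               "pairs")
  expect_error(combined_cost(tr, inputs[-2], metric_weights(0, 1, 0)),
               "roi_fixed")
})

test_that("parzen MI agrees with dense MI in rank and sign behavior", {
  # parzen and dense are different estimators of the same quantity;
  # aligned volumes must beat misaligned ones under both
  f <- rand_volume(16, seed = 8, spacing = c(1, 1, 1))
  pts <- voxel_to_world(f, as.matrix(expand.grid(2:13, 2:13, 2:13)))
  aligned <- mutual_information(identity_transform(), f, f,
                                mi_config(n_bins = 16), samples = pts)
  shifted <- mutual_information(affine_transform(translation = c(2, 1, 0)),
                                f, f, mi_config(n_bins = 16),
                                samples = pts)
  expect_gt(aligned$mi, shifted$mi)
  expect_gt(aligned$mi, 0)
})

test_that("analytic gradients match central differences", {
  fixed <- rand_volume(16, seed = 42)
  moving <- rand_volume(16, seed = 43)
  tr <- rand_bspline_transform(fixed, seed = 7)
  pts <- voxel_to_world(fixed, as.matrix(expand.grid(3:12, 3:12, 3:12)))
  roi_f <- sphere_mask(c(16, 16, 16), c(8, 8, 8), 4)
  roi_m <- sphere_mask(c(16, 16, 16), c(9, 7, 8), 4)
  set.seed(3)
  prs <- paired_points(matrix(runif(30, 3, 12), 10, 3),
                       matrix(runif(30, 3, 12), 10, 3))
  fns <- list(
    mi = function(t, g = FALSE)
      mutual_information(t, fixed, moving, mi_config(n_bins = 16),
                         samples = pts, gradient = g),
    fiducial = function(t, g = FALSE) fiducial_cost(t, prs, gradient = g),
    kappa = function(t, g = FALSE)
      kappa_cost(t, roi_f, roi_m, gradient = g, samples = pts))
  h <- 1e-4
  for (nm in names(fns)) {
    fn <- fns[[nm]]
    g <- fn(tr, TRUE)$gradient
    set.seed(99)
    sel <- sample(length(g), 20)
    num <- vapply(sel, function(s) {
      t1 <- tr; t2 <- tr
      t1$bspline$coefficients[s] <- t1$bspline$coefficients[s] + h
      t2$bspline$coefficients[s] <- t2$bspline$coefficients[s] - h
      (fn(t1)$value - fn(t2)$value) / (2 * h)
    }, 0)
    rel <- sqrt(sum((g[sel] - num)^2)) / max(sqrt(sum(num^2)), 1e-12)
    expect_lt(rel, 1e-3)
  }
})

test_that("the fused optimizer objective equals the public combined cost", {
  fixed <- rand_volume(16, seed = 42)
  moving <- rand_volume(16, seed = 43)
  tr <- rand_bspline_transform(fixed, seed = 7)
  ar <- as.matrix(expand.grid(3:12, 3:12, 3:12))
  pts <- voxel_to_world(fixed, ar)
  fvals <- fixed$data[ar + 1]
  roi_f <- sphere_mask(c(16, 16, 16), c(8, 8, 8), 4)
  roi_m <- sphere_mask(c(16, 16, 16), c(9, 7, 8), 4)
  set.seed(3)
  prs <- paired_points(matrix(runif(30, 3, 12), 10, 3),
                       matrix(runif(30, 3, 12), 10, 3))
  w <- metric_weights(1, 1, 100)
  micfg <- mi_config(n_bins = 16)
  micfg$fixed_range <- quantile(fixed$data, micfg$range_quantiles,
                                names = FALSE)
  micfg$moving_range <- quantile(moving$data, micfg$range_quantiles,
                                 names = FALSE)
  kA <- mmdir:::.trilinear_vol(roi_f, pts)$value
  fused <- mmdir:::.fused_objective(
    tr, unclass(w),
    list(mi = list(pts = pts, f = fvals),
         kappa = list(pts = pts, A = kA), pairs = prs),
    micfg, moving, roi_m)
  pub <- combined_cost(tr, list(pairs = prs, roi_fixed = roi_f,
                                roi_moving = roi_m, fixed = fixed,
                                moving = moving),
                       w, cfg = micfg, gradient = TRUE, mi_samples = pts,
                       kappa_samples = pts, kappa_values = kA)
  expect_equal(fused$value, pub$value, tolerance = 1e-14)
  expect_equal(max(abs(fused$gradient - pub$gradient)), 0,
               tolerance = 1e-12)
})
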