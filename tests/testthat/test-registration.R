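# Pyramid, optimizer, affine stage and the multi-metric pipeline.

test_that("gaussian pyramid: constants, shapes, convolution oracle", {
  cv <- volume(array(7, c(64, 64, 64)))
  pyr <- gaussian_pyramid(cv, 3, factors = c(4, 2, 1))
  expect_equal(vapply(pyr, function(v) dim(v$data)[1], 1L), c(16L, 32L, 64L))
  for (lv in pyr) expect_true(all(abs(lv$data - 7) < 1e-12))
  expect_equal(pyr[[1]]$spacing, cv$spacing * 4)
  expect_equal(pyr[[1]]$origin, cv$origin)

  # impulse: the coarse level equals Gaussian-filter-then-subsample
  im <- volume(array(0, c(32, 32, 32)))
  im$data[17, 17, 17] <- 1
  pyr <- gaussian_pyramid(im, 2, factors = c(2, 1))
  s <- 1                                   # sigma = factor / 2
  r <- ceiling(4 * s)
  k <- dnorm(-r:r, sd = s); k <- k / sum(k)
  # direct separable convolution oracle at probe voxels near the impulse
  conv_at <- function(i, j, kk) {
    acc <- 0
    for (a in -r:r) for (b in -r:r) for (cc in -r:r) {
      if (i - a == 17 && j - b == 17 && kk - cc == 17)
        acc <- acc + k[a + r + 1] * k[b + r + 1] * k[cc + r + 1]
    }
    acc
  }
  for (probe in list(c(17, 17, 17), c(19, 17, 17), c(17, 15, 19))) {
    want <- conv_at(probe[1], probe[2], probe[3])
    got <- pyr[[1]]$data[(probe[1] + 1) / 2, (probe[2] + 1) / 2,
                         (probe[3] + 1) / 2]
    # probe voxels chosen on the subsample lattice (odd indices)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("sgd_minimize solves a quadratic bowl and is deterministic", {
  cc <- c(2, -1, 3, 0.5)
  fn <- function(p, it) list(value = sum((p - cc)^2),
                             gradient = 2 * (p - cc))
  r <- sgd_minimize(fn, rep(0, 4), max_iter = 500, step0 = 1)
  expect_equal(r$par, cc, tolerance = 1e-3)
  expect_lte(r$iterations, 500)
  # stationary start returns immediately
  r0 <- sgd_minimize(fn, cc, max_iter = 100)
  expect_equal(r0$iterations, 1L)
  expect_identical(r0$par, cc)
  # bit-identical repeat
  r2 <- sgd_minimize(fn, rep(0, 4), max_iter = 500, step0 = 1)
  expect_identical(r$par, r2$par)
  expect_identical(r$trace, r2$trace)
  # non-finite propagation carries the iteration index
  bad <- function(p, it) list(value = if (it >= 3) NaN else 1,
                              gradient = rep(1, 4))
  expect_error(sgd_minimize(bad, rep(0, 4)), "iteration 3")
})

# analytic scene (ball + smooth internal bumps) sampled on the grid;
# building both images from the same continuous function avoids the
# resampling blur asymmetry a trilinear-warped copy would carry
analytic_scene <- function(n = 48, spacing = 2, seed = 1) {
  set.seed(seed)
  ctr <- rep((n - 1) * spacing / 2, 3)
  rad <- 0.33 * n * spacing
  nb <- 40
  bc <- matrix(rnorm(3 * nb, mean = ctr[1], sd = rad / 2.2), nb, 3)
  ba <- runif(nb, 60, 160)
  scene <- function(pts) {
    r <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
    inside <- pmin(pmax((rad - r) / 4, 0), 1)   # smooth 4 mm edge
    val <- rep(-100, nrow(pts))
    for (b in seq_len(nb)) {
      d2 <- rowSums(sweep(pts, 2, bc[b, ])^2)
      val <- val + ba[b] * exp(-d2 / (2 * 4^2))
    }
    -1000 + inside * (val + 900)
  }
  grid <- as.matrix(expand.grid(0:(n - 1), 0:(n - 1), 0:(n - 1))) * spacing
  list(scene = scene, grid = grid, ctr = ctr, n = n, spacing = spacing)
}

test_that("affine registration recovers identity, shift and scale", {
  sc <- analytic_scene()
  as_vol <- function(vals) volume(array(vals, rep(sc$n, 3)),
                                  spacing = rep(sc$spacing, 3))
  v <- as_vol(sc$scene(sc$grid))
  cfg <- registration_config(affine_samples = 4000, seed = 2)
  a0 <- register_affine(v, v, cfg)
  expect_lt(sqrt(sum(a0$translation^2)), 0.5 * min(v$spacing))
  expect_lt(max(abs(a0$matrix - diag(3))), 0.01)

  # moving = fixed translated by `shift`: moving(x) = scene(x - shift),
  # so the backward fixed-to-moving map to recover is T(x) = x + shift
  shift <- c(6, -4, 5)
  vs <- as_vol(sc$scene(sweep(sc$grid, 2, shift)))
  as <- register_affine(v, vs, cfg)
  ctr <- matrix(sc$ctr, 1)
  got <- drop(apply_transform_points(as, ctr)) - drop(ctr)
  expect_lt(max(abs(got - shift)), 1)   # within 1 mm per axis

  # moving = fixed scaled by 1.05 about the center: the backward mapping
  # has linear part 1.05 I
  sgrid <- sweep(sweep(sc$grid, 2, sc$ctr) / 1.05, 2, sc$ctr, "+")
  vsc <- as_vol(sc$scene(sgrid))
  asc <- register_affine(v, vsc, cfg)
  expect_lt(max(abs(diag(asc$matrix) - 1.05)), 0.05 * 0.2)  # within 1%
})

test_that("self-registration with default weights is near-identity", {
  ph <- generate_phantom(small_phantom_config(seed = 2, amplitude = 0,
                                              resection = FALSE,
                                              noise_sd = 5))
  set.seed(9)
  prs <- ph$landmarks
  reg <- register_multimetric(ph$fixed, ph$fixed, smoke_reg_config(seed = 3),
                              pairs = paired_points(prs$fixed, prs$fixed),
                              roi_fixed = ph$gland_fixed,
                              roi_moving = ph$gland_fixed,
                              fixed_mask = ph$body_fixed)
  tre <- target_registration_error(
    paired_points(prs$fixed, prs$fixed), reg$transform)
  expect_lt(median(tre$per_point$distance), 0.5 * min(ph$fixed$spacing))
  # dense-mode cost never increases across a level (safeguard contract)
  for (li in reg$levels) expect_lte(li$dense_end, li$dense_start + 1e-9)
})

test_that("intensity-only weights ignore pairs and ROIs (one code path)", {
  ph <- generate_phantom(small_phantom_config(seed = 4, amplitude = 5,
                                              resection = FALSE))
  cfg <- smoke_reg_config(seed = 5, weights = metric_weights(0, 0, 1))
  r1 <- register_multimetric(ph$fixed, ph$moving, cfg,
                             pairs = ph$landmarks,
                             roi_fixed = ph$gland_fixed,
                             roi_moving = ph$gland_moving,
                             fixed_mask = ph$body_fixed)
  r2 <- register_multimetric(ph$fixed, ph$moving, cfg,
                             fixed_mask = ph$body_fixed)
  expect_identical(r1$transform$bspline$coefficients,
                   r2$transform$bspline$coefficients)
  expect_identical(r1$affine$matrix, r2$affine$matrix)
})

test_that("the pipeline is bit-reproducible given a seed", {
  ph <- generate_phantom(small_phantom_config(seed = 6, amplitude = 5,
                                              resection = FALSE))
  cfg <- smoke_reg_config(seed = 7)
  run <- function() register_multimetric(
    ph$fixed, ph$moving, cfg, pairs = ph$landmarks,
    roi_fixed = ph$gland_fixed, roi_moving = ph$gland_moving,
    fixed_mask = ph$body_fixed)
  r1 <- run(); r2 <- run()
  expect_identical(r1$transform$bspline$coefficients,
                   r2$transform$bspline$coefficients)
  expect_identical(r1$final_metrics, r2$final_metrics)
})

test_that("missing inputs for a weighted metric are rejected", {
  ph <- generate_phantom(small_phantom_config(seed = 8, amplitude = 3,
                                              resection = FALSE))
  expect_error(register_multimetric(ph$fixed, ph$moving,
                                    smoke_reg_config(seed = 1)),
               "fiducial metric requires")
  expect_error(register_multimetric(
    ph$fixed, ph$moving,
    smoke_reg_config(seed = 1, weights = metric_weights(0, 1, 1))),
    "region metric requires")
})

test_that("config validation enforces the level structure", {
  expect_error(registration_config(levels = 0), "levels")
  expect_error(registration_config(factors = c(4, 2, 2)), "end at 1")
  expect_error(registration_config(grid_spacing = c(40, 20, 12)), "halve")
  expect_error(registration_config(grid_spacing = c(48, 24)), "one control")
})
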