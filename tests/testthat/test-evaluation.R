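# TRE, Dice, Hausdorff, checkerboard and overlay.

test_that("TRE matches closed forms, a loop oracle, and recomputes", {
  p <- matrix(runif(18, 0, 10), 6, 3)
  tre0 <- target_registration_error(paired_points(p, p),
                                    identity_transform())
  expect_true(all(tre0$per_point$distance == 0))

  two <- paired_points(matrix(0, 2, 3),
                       rbind(c(3, 4, 0), c(0, 0, 5)))
  tre <- target_registration_error(two, identity_transform())
  expect_equal(tre$per_point$distance, c(5, 5))
  expect_equal(tre$groups$mean, 5)

  set.seed(12)
  q <- matrix(runif(18, 0, 10), 6, 3)
  aff <- affine_transform(diag(3) + matrix(rnorm(9, 0, 0.02), 3), rnorm(3))
  groups <- c("soft_tissue", "soft_tissue", "rigid", "rigid",
              "boundary", "boundary")
  tre2 <- target_registration_error(paired_points(p, q, groups), aff)
  for (i in 1:6) {
    want <- sqrt(sum((q[i, ] - (aff$matrix %*% p[i, ] +
                                  aff$translation))^2))
    expect_equal(tre2$per_point$distance[i], want, tolerance = 1e-12)
  }
  # group means are recomputable from the listed per-point distances
  for (g in unique(groups)) {
    idx <- tre2$per_point$group == g
    gi <- match(g, tre2$groups$group)
    expect_equal(tre2$groups$mean[gi],
                 mean(tre2$per_point$distance[idx]))
    expect_equal(tre2$groups$n[gi], sum(idx))
  }
})

test_that("dice matches its closed forms and contracts", {
  dims <- c(10, 10, 10)
  a <- sphere_mask(dims, c(5, 5, 5), 3)
  expect_equal(dice(a, a), 1)
  b <- sphere_mask(dims, c(2, 2, 2), 1)
  c2 <- sphere_mask(dims, c(8, 8, 8), 1)
  expect_equal(dice(b, c2), 0)
  # |A| = 6, |B| = 2, overlap 2 -> 0.5
  A <- array(FALSE, dims); B <- array(FALSE, dims)
  A[1:6, 1, 1] <- TRUE; B[5:6, 1, 1] <- TRUE
  expect_equal(dice(label_mask(A), label_mask(B)), 0.5)
  expect_equal(dice(label_mask(A), label_mask(B)),
               dice(label_mask(B), label_mask(A)))
  e <- label_mask(array(FALSE, dims))
  expect_error(dice(e, e), "undefined DSC")
  expect_error(dice(a, sphere_mask(c(9, 10, 10), c(5, 5, 5), 3)),
               "geometry")
})

test_that("hausdorff matches closed forms and an all-pairs oracle", {
  dims <- c(10, 10, 12)
  sp <- c(1, 1, 1)
  a <- sphere_mask(dims, c(5, 5, 6), 3, spacing = sp)
  expect_equal(hausdorff(a, a), 0)
  # two single-voxel masks at a 3-4-5 offset
  A <- array(FALSE, dims); B <- array(FALSE, dims)
  A[2, 2, 2] <- TRUE; B[5, 6, 2] <- TRUE
  expect_equal(hausdorff(label_mask(A, spacing = sp),
                         label_mask(B, spacing = sp)), 5)
  # random masks vs brute-force max-min over boundary voxel coordinates
  for (seed in 1:6) {
    m1 <- rand_mask(dims, seed = seed, spacing = c(1.5, 1, 2))
    m2 <- rand_mask(dims, seed = seed + 40, spacing = c(1.5, 1, 2))
    got <- hausdorff(m1, m2)
    bnd <- function(m) {
      w <- which(mmdir:::.boundary_mask(m), arr.ind = TRUE) - 1
      sweep(w, 2, m$spacing, "*")
    }
    p1 <- bnd(m1); p2 <- bnd(m2)
    h <- function(x, y) max(apply(x, 1, function(r)
      min(sqrt(colSums((t(y) - r)^2)))))
    expect_equal(got, max(h(p1, p2), h(p2, p1)), tolerance = 1e-9)
    expect_equal(got, hausdorff(m2, m1))
  }
  expect_error(hausdorff(a, label_mask(array(FALSE, dims), spacing = sp)),
               "empty")
})

test_that("dice/hausdorff are invariant to joint axis permutation", {
  m1 <- rand_mask(c(9, 11, 10), seed = 3)
  m2 <- rand_mask(c(9, 11, 10), seed = 4)
  perm <- function(m) label_mask(aperm(m$data, c(3, 1, 2)),
                                 spacing = m$spacing[c(3, 1, 2)])
  expect_equal(dice(m1, m2), dice(perm(m1), perm(m2)))
  expect_equal(hausdorff(m1, m2), hausdorff(perm(m1), perm(m2)))
})

test_that("hard kappa and dice coincide on identical inputs", {
  a <- rand_mask(c(12, 12, 12), seed = 6)
  b <- rand_mask(c(12, 12, 12), seed = 7)
  expect_equal(kappa_statistic(identity_transform(), a, b), dice(a, b))
})

test_that("checkerboard alternates tiles by index parity", {
  f <- rand_volume(8, seed = 1)
  m <- rand_volume(8, seed = 2)
  expect_identical(checkerboard(f, f, 4)$data, f$data)
  expect_identical(checkerboard(f, m, 8)$data, f$data)  # one even tile
  cb <- checkerboard(volume(array(0, c(8, 8, 8))),
                     volume(array(1, c(8, 8, 8))), 2)
  idx <- as.matrix(expand.grid(0:7, 0:7, 0:7))
  parity <- (idx[, 1] %/% 2 + idx[, 2] %/% 2 + idx[, 3] %/% 2) %% 2
  expect_identical(as.vector(cb$data), as.double(parity))
  expect_error(checkerboard(f, rand_volume(9, seed = 3)), "geometry")
})

test_that("overlay renders agreement as gray, disagreement as color", {
  f <- rand_volume(6, seed = 4, mean = 100, sd = 30)
  ov <- overlay(f, f)
  expect_true(all(abs(ov[, , , 1] - ov[, , , 2]) < 1e-12))
  expect_true(all(abs(ov[, , , 2] - ov[, , , 3]) < 1e-12))
  # moved = 0 where fixed > 0 -> pure orange (R > 0, B = 0)
  z <- volume(array(0, dim(f$data)), f$spacing)
  ov2 <- overlay(f, z, window = c(0, max(f$data)))
  bright <- f$data > 0
  expect_true(all(ov2[, , , 3][bright] == 0))
  expect_true(all(ov2[, , , 1][bright] > 0))
  # channel arithmetic equals the per-pixel formula
  w <- c(20, 120)
  ov3 <- overlay(f, z, window = w)
  wf <- pmin(pmax((f$data - w[1]) / diff(w), 0), 1)
  expect_equal(as.vector(ov3[, , , 1]), as.vector(wf))
  expect_equal(as.vector(ov3[, , , 2]), as.vector(wf / 2))
  pngf <- tempfile(fileext = ".png")
  write_slice_png(ov3, 3, pngf)
  expect_true(file.size(pngf) > 0)
})
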