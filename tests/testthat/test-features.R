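# Harris corners, correlation point matching, Otsu segmentation.

test_that("harris finds nothing in a constant volume", {
  v <- volume(array(3, c(12, 12, 12)))
  expect_equal(nrow(harris_corners_3d(v)), 0)
})

test_that("harris localizes the corners of a bright cube", {
  v <- volume(array(0, c(24, 24, 24)))
  v$data[9:16, 9:16, 9:16] <- 100
  pts <- harris_corners_3d(v, n_points = 8)
  expect_equal(nrow(pts), 8)
  corners <- as.matrix(expand.grid(c(8, 15), c(8, 15), c(8, 15)))
  for (i in seq_len(nrow(pts))) {
    d <- sqrt(rowSums(sweep(corners, 2, pts[i, ])^2))
    expect_lt(min(d), 2)
  }
})

test_that("harris response matches an explicit structure-tensor oracle", {
  v <- rand_volume(14, seed = 31, spacing = c(1, 1, 1))
  sg <- 1.0; sw <- 1.6; k <- 0.001
  # independent oracle: direct convolution loops over the same kernels
  gauss3 <- function(a, s) {
    r <- ceiling(4 * s)
    kk <- dnorm(-r:r, sd = s); kk <- kk / sum(kk)
    d <- dim(a)
    refl <- function(i, n) ifelse(i < 1, 2 - i, ifelse(i > n, 2 * n - i, i))
    out <- a
    for (ax in 1:3) {
      src <- out; out <- array(0, d)
      for (o in -r:r) {
        idx <- lapply(d, seq_len)
        idx[[ax]] <- refl(idx[[ax]] + o, d[ax])
        out <- out + kk[o + r + 1] * do.call(`[`, c(list(src), idx))
      }
    }
    out
  }
  sm <- gauss3(v$data, sg)
  d <- dim(sm)
  cgrad <- function(a, ax) {
    n <- d[ax]
    hi <- lapply(d, seq_len); lo <- hi
    hi[[ax]] <- pmin(hi[[ax]] + 1, n); lo[[ax]] <- pmax(lo[[ax]] - 1, 1)
    den <- array(2, d)
    if (ax == 1) { den[1, , ] <- 1; den[n, , ] <- 1 }
    if (ax == 2) { den[, 1, ] <- 1; den[, n, ] <- 1 }
    if (ax == 3) { den[, , 1] <- 1; den[, , n] <- 1 }
    (do.call(`[`, c(list(a), hi)) - do.call(`[`, c(list(a), lo))) / den
  }
  gx <- cgrad(sm, 1); gy <- cgrad(sm, 2); gz <- cgrad(sm, 3)
  Axx <- gauss3(gx * gx, sw); Ayy <- gauss3(gy * gy, sw)
  Azz <- gauss3(gz * gz, sw); Axy <- gauss3(gx * gy, sw)
  Axz <- gauss3(gx * gz, sw); Ayz <- gauss3(gy * gz, sw)
  detM <- Axx * (Ayy * Azz - Ayz^2) - Axy * (Axy * Azz - Ayz * Axz) +
    Axz * (Axy * Ayz - Ayy * Axz)
  R_oracle <- detM - k * (Axx + Ayy + Azz)^3

  R_pkg <- mmdir:::.harris_response(v, sg, sw, k)
  rel <- max(abs(R_pkg - R_oracle)) / max(abs(R_oracle))
  expect_lt(rel, 1e-6)
})

test_that("harris is equivariant to axis permutation of isotropic volumes", {
  v <- rand_volume(12, seed = 5)
  p1 <- harris_corners_3d(v, n_points = 6)
  vp <- volume(aperm(v$data, c(2, 3, 1)))
  p2 <- harris_corners_3d(vp, n_points = 6)
  # permuting (x,y,z) -> (y,z,x) of the volume permutes corner coordinates
  p1_perm <- p1[, c(2, 3, 1), drop = FALSE]
  key <- function(m) sort(apply(round(m, 9), 1, paste, collapse = ","))
  expect_identical(key(p1_perm), key(p2))
})

test_that("match_points recovers known correspondences and rejects noise", {
  v <- rand_volume(24, seed = 21, spacing = c(1, 1, 1))
  sm <- volume(mmdir:::.smooth_gaussian(v$data, 1.2), v$spacing)
  pts <- voxel_to_world(sm, as.matrix(expand.grid(c(8, 12, 16),
                                                  c(8, 12, 16), 12)))
  # identical images: every point maps to itself
  pr <- match_points(sm, sm, pts, search_radius_mm = 5, patch_radius_mm = 4,
                     max_inconsistency_mm = Inf)
  expect_equal(nrow(pr$fixed), nrow(pts))
  expect_lt(max(abs(pr$moving - pr$fixed)), 1e-9)
  # known integer shift
  shifted <- resample_volume(sm, sm, affine_transform(translation = c(2, 0, 0)))
  pr2 <- match_points(shifted, sm, pts, search_radius_mm = 5,
                      patch_radius_mm = 4, max_inconsistency_mm = Inf)
  disp <- pr2$moving - pr2$fixed
  expect_lt(max(abs(sweep(disp, 2, c(2, 0, 0)))), 0.5)
  # matched points never leave the moving volume
  vox <- world_to_voxel(sm, pr2$moving)
  expect_true(all(vox >= 0 & vox <= 23))
  # independent noise cannot produce reliable pairs
  other <- rand_volume(24, seed = 99, spacing = c(1, 1, 1))
  expect_error(match_points(sm, other, pts, search_radius_mm = 4,
                            patch_radius_mm = 4, min_corr = 0.5,
                            max_inconsistency_mm = Inf),
               "no reliable pairs")
})

test_that("otsu segmentation: separable case, bimodal case, contracts", {
  set.seed(8)
  arr <- array(0, c(16, 16, 16))
  arr[sample(length(arr), 400)] <- 100
  v <- volume(arr)
  seg <- threshold_segment(v)
  # perfectly separable: foreground is exactly the bright voxels of the
  # largest connected component
  expect_true(all(v$data[seg$data] == 100))
  lab <- array(mmdir:::.cpp_label_components(arr == 100, dim(arr)),
               dim(arr))
  big <- which.max(tabulate(lab[lab > 0]))
  expect_identical(seg$data, lab == big)

  # bimodal mixture: threshold lands between the modes
  set.seed(9)
  vals <- c(rnorm(2000, 30, 5), rnorm(2000, 90, 5))
  thr <- mmdir:::.otsu_threshold(vals, 256)
  expect_gt(thr, 45); expect_lt(thr, 75)
  # exhaustive search oracle over the same histogram bins
  r <- range(vals); nb <- 256
  h <- tabulate(pmin(floor((vals - r[1]) / diff(r) * nb), nb - 1) + 1, nb)
  mids <- r[1] + (seq_len(nb) - 0.5) * diff(r) / nb
  best <- -Inf; bt <- NA
  for (t in 1:(nb - 1)) {
    w0 <- sum(h[1:t]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:t] * mids[1:t]) / w0
    mu1 <- sum(h[(t + 1):nb] * mids[(t + 1):nb]) / w1
    v2 <- w0 * w1 * (mu0 - mu1)^2
    if (v2 > best) { best <- v2; bt <- r[1] + t * diff(r) / nb }
  }
  expect_equal(thr, bt)

  expect_error(threshold_segment(volume(array(5, c(8, 8, 8)))),
               "degenerate histogram")
})

test_that("otsu segmentation is idempotent on its own output", {
  ph <- generate_phantom(small_phantom_config(seed = 3, resection = FALSE))
  seg1 <- threshold_segment(ph$moving, mask = ph$body_moving,
                            closing_mm = 3)
  two_level <- volume(array(as.double(seg1$data), dim(seg1$data)),
                      seg1$spacing)
  seg2 <- threshold_segment(two_level, closing_mm = 3)
  expect_identical(seg2$data, seg1$data)
})
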