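# Geometric data model: coordinate conversions, transforms, construction
# contracts, file round-trips.

test_that("world/voxel conversion matches the stated examples and inverts", {
  v <- volume(array(0, c(8, 8, 8)))
  expect_equal(drop(world_to_voxel(v, c(3, 4, 5))), c(3, 4, 5),
               ignore_attr = TRUE)
  v2 <- volume(array(0, c(8, 8, 8)), spacing = c(2, 2, 5),
               origin = c(10, 0, 0))
  expect_equal(drop(world_to_voxel(v2, c(14, 2, 5))), c(2, 1, 1),
               ignore_attr = TRUE)
  set.seed(1)
  p <- matrix(runif(300, -20, 60), 100, 3)
  rt <- voxel_to_world(v2, world_to_voxel(v2, p))
  expect_lt(max(abs(rt - p)), 1e-9)
})

test_that("construction contracts reject invalid inputs", {
  expect_error(volume(array(c(NA, rep(0, 7)), c(2, 2, 2))), "non-finite")
  expect_error(volume(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
  expect_error(label_mask(array(2, c(2, 2, 2))), "0 or 1")
  # geometry mismatch is rejected at construction, never resampled
  v <- volume(array(0, c(4, 4, 4)))
  expect_error(label_mask(array(TRUE, c(3, 4, 4)), like = v),
               "do not match")
  expect_error(paired_points(matrix(0, 2, 3), matrix(0, 3, 3)), "equal")
  expect_error(paired_points(matrix(0, 1, 3), matrix(0, 1, 3), "bones"),
               "group")
})

test_that("transform application: identity, translation, partition of unity", {
  v <- volume(array(0, c(10, 10, 10)), spacing = c(1.5, 1.5, 3))
  pts <- voxel_to_world(v, as.matrix(expand.grid(0:9, 0:9, 0:9)))
  b0 <- bspline_grid_for(v, 6)
  expect_identical(apply_transform_points(b0, pts), pts)  # mu = 0, bit-exact
  aff <- affine_transform(translation = c(1, 2, 3))
  expect_equal(drop(apply_transform_points(aff, c(0, 0, 0))), c(1, 2, 3),
               ignore_attr = TRUE)
  # uniform coefficients displace every fully supported point equally
  b <- b0
  b$coefficients[] <- rep(c(2, -1, 0.5), each = prod(b$grid_dim))
  disp <- apply_transform_points(b, pts) - pts
  expect_lt(max(abs(sweep(disp, 2, c(2, -1, 0.5)))), 1e-9)
})

test_that("composite with identity parts is the identity", {
  v <- volume(array(0, c(6, 6, 6)))
  pts <- matrix(runif(30, 0, 5), 10, 3)
  tr <- composite_transform(affine_transform(), bspline_grid_for(v, 3))
  expect_identical(apply_transform_points(tr, pts), pts)
  expect_identical(apply_transform_points(identity_transform(), pts), pts)
})

test_that("affine transforms must be invertible", {
  m <- diag(3); m[1, 1] <- 0
  expect_error(affine_transform(m), "singular")
})

test_that("dyadic grid refinement preserves the displacement field", {
  v <- volume(array(0, c(12, 12, 12)), spacing = c(2, 2, 2))
  b <- bspline_grid_for(v, 8)
  set.seed(3)
  b$coefficients[] <- runif(length(b$coefficients), -4, 4)
  b2 <- refine_bspline(b)
  expect_equal(b2$grid_spacing, b$grid_spacing / 2)
  pts <- voxel_to_world(v, as.matrix(expand.grid(0:11, 0:11, 0:11)))
  err <- abs(apply_transform_points(b, pts) -
               apply_transform_points(b2, pts))
  expect_lt(max(err), 0.1)   # contract bound; actual error is ~1e-12
  expect_lt(max(err), 1e-9)
})

test_that("MetaImage round-trips volumes and masks bit-exactly", {
  v <- rand_volume(6, seed = 9, spacing = c(0.68, 1.37, 5),
                   origin = c(-20.25, 3.5, 7))
  for (ext in c(".mha", ".mhd")) {
    p <- tempfile(fileext = ext)
    write_metaimage(v, p)
    v2 <- read_metaimage(p)
    expect_identical(v2$data, v$data)
    expect_identical(v2$spacing, v$spacing)
    expect_identical(v2$origin, v$origin)
  }
  m <- sphere_mask(c(6, 6, 6), c(3, 3, 3), 2)
  p <- tempfile(fileext = ".mha")
  write_metaimage(m, p)
  expect_identical(read_metaimage(p, as_mask = TRUE)$data, m$data)
})

test_that("NIfTI round-trips data exactly and geometry to float precision", {
  v <- rand_volume(5, seed = 2, spacing = c(1.5, 1.5, 3),
                   origin = c(-10, 4.25, 0))
  for (ext in c(".nii", ".nii.gz")) {
    p <- tempfile(fileext = ext)
    write_nifti(v, p)
    v2 <- read_nifti(p)
    expect_identical(v2$data, v$data)
    expect_identical(v2$spacing, v$spacing)  # representable in float32
    expect_identical(v2$origin, v$origin)
  }
})

test_that("point sets and transforms round-trip through their files", {
  set.seed(4)
  pts <- matrix(rnorm(45, 10, 40), 15, 3)
  p <- tempfile(fileext = ".txt")
  write_point_set(pts, p)
  expect_identical(read_point_set(p), pts)
  expect_error(read_point_set(tempfile()), "cannot open|No such")

  v <- volume(array(0, c(8, 8, 8)), spacing = c(1.5, 1.5, 3))
  b <- bspline_grid_for(v, 5)
  set.seed(5)
  b$coefficients[] <- rnorm(length(b$coefficients))
  tr <- composite_transform(affine_transform(diag(3) * 1.01, c(1, -2, 3)), b)
  tf <- tempfile(fileext = ".json")
  write_transform(tr, tf)
  tr2 <- read_transform(tf)
  expect_identical(tr2$bspline$coefficients, b$coefficients)
  expect_identical(tr2$affine$matrix, tr$affine$matrix)
  expect_identical(tr2$affine$translation, tr$affine$translation)
})
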