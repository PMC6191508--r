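test_that("patch extraction replicates edges and honors the radius", {
  v <- rand_volume(c(10, 10, 10), seed = 7)
  p <- extract_patch(v, c(5, 5, 5), r_s = 3)
  expect_equal(dim(p), c(7, 7, 7))
  expect_equal(p[4, 4, 4], v$data[6, 6, 6])

  corner <- extract_patch(v, c(0, 0, 0), r_s = 3)
  expect_equal(dim(corner), c(7, 7, 7))
  expect_equal(corner[1, 1, 1], v$data[1, 1, 1])  # replicated corner

  expect_equal(dim(extract_patch(v, c(4, 4, 4), r_s = 0)), c(1, 1, 1))
  expect_error(extract_patch(v, c(10, 0, 0), r_s = 1),
               class = "atlasfuse_bad_voxel")
})

test_that("patch normalization is a guarded z-score", {
  expect_equal(normalize_patch(array(5, c(3, 3, 3))), array(0, c(3, 3, 3)))
  set.seed(8)
  p <- array(rnorm(343, 10, 4), c(7, 7, 7))
  z <- normalize_patch(p)
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(sd(z) - 1), 1e-6)
  expect_equal(normalize_patch(2 * p + 5), z, tolerance = 1e-12)
})

test_that("filter bank kernels behave on ramps and impulses", {
  zero <- filter_bank(array(0, c(7, 7, 7)))
  expect_true(all(vapply(zero, function(r) all(r == 0), logical(1))))

  # axis-aligned linear ramp: second differences and Laplacian vanish in
  # the interior; first difference along the ramp is twice the slope
  ramp <- array(rep(1:7, times = 49), c(7, 7, 7))
  fb <- filter_bank(ramp)
  inner <- 2:6
  expect_equal(fb$d2_x[inner, inner, inner], array(0, c(5, 5, 5)))
  expect_equal(fb$laplacian[inner, inner, inner], array(0, c(5, 5, 5)))
  expect_equal(fb$d1_x[inner, inner, inner], array(2, c(5, 5, 5)))

  # impulse at the center: Sobel response reads off the mirrored kernel
  imp <- array(0, c(7, 7, 7))
  imp[4, 4, 4] <- 1
  fbi <- filter_bank(imp)
  # at offset (-1, 0, 0) from the impulse the x-Sobel tap is dx * w[dy] *
  # w[dz] evaluated at (1, 0, 0), i.e. 1 * 2 * 2
  expect_equal(fbi$sobel_x[3, 4, 4], 4)
  expect_equal(fbi$sobel_x[5, 4, 4], -4)
  expect_equal(fbi$sobel_x[4, 4, 4], 0)
  expect_equal(fbi$laplacian[4, 4, 4], -26)
  expect_equal(fbi$range[4, 4, 4], 1)
})

test_that("compiled feature vectors equal the R reference composition", {
  v <- rand_volume(c(9, 9, 9), seed = 13)
  for (vox in list(c(4, 4, 4), c(0, 0, 0), c(8, 2, 7))) {
    z <- normalize_patch(extract_patch(v, vox, r_s = 3))
    ref <- c(as.numeric(z),
             unlist(lapply(filter_bank(z), as.numeric), use.names = FALSE))
    got <- extract_feature_vector(v, vox, patch_params(r_s = 3))
    # R's mean()/sd() accumulate in long double; agreement is to
    # round-off, not bitwise
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("feature layout fixes the vector length and block order", {
  lay <- feature_layout(r_s = 3)
  expect_equal(sum(lay$length), 15 * 343)
  expect_equal(lay$block[1], "intensity")
  expect_equal(length(extract_feature_vector(rand_volume(c(8, 8, 8)),
                                             c(4, 4, 4))), sum(lay$length))
  # golden layout: any reordering of the blocks would break this
  expect_equal(lay$block,
               c("intensity", "d1_x", "d1_y", "d1_z", "d2_x", "d2_y", "d2_z",
                 "hyperplane_x", "hyperplane_y", "hyperplane_z",
                 "sobel_x", "sobel_y", "sobel_z", "laplacian", "range"))
})

test_that("features are deterministic and affine-invariant", {
  v <- rand_volume(c(9, 9, 9), seed = 17)
  f1 <- extract_feature_vector(v, c(4, 4, 4))
  f2 <- extract_feature_vector(v, c(4, 4, 4))
  expect_identical(f1, f2)

  w <- volume(3 * v$data + 40, spacing = v$spacing)
  expect_equal(extract_feature_vector(w, c(4, 4, 4)), f1, tolerance = 1e-9)

  # identical patches at different locations give identical vectors
  con <- volume(array(100, c(9, 9, 9)))
  expect_identical(extract_feature_vector(con, c(2, 2, 2), patch_params(r_s = 1)),
                   extract_feature_vector(con, c(6, 6, 6), patch_params(r_s = 1)))
})
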