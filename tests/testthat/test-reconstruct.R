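test_that("reconstruction is linear and zero-preserving", {
  ps <- fix_projections()
  z0 <- ps
  z0$images[] <- 0
  expect_true(all(reconstruct(z0)$voxels == 0))
  r1 <- reconstruct_slice(ps$images[24, , ], ps$angles)
  r3 <- reconstruct_slice(3 * ps$images[24, , ], ps$angles)
  expect_equal(r3, 3 * r1, tolerance = 1e-10)
})

test_that("an impulse phantom reconstructs at its own voxel", {
  ph <- generate_phantom(64, 0, seed = 1)
  v <- array(0, dim = c(64, 64, 64))
  v[41, 27, 30] <- 1
  ph$voxels <- v
  ps <- forward_project(ph, seq(0, 180, length.out = 91),
                        method = "discrete")
  rec <- reconstruct_slice(ps$images[30, , ], ps$angles)
  expect_equal(as.vector(arrayInd(which.max(rec), dim(rec))), c(41, 27))
})

test_that("project-then-reconstruct recovers the phantom", {
  ph <- fix_phantom()
  ps <- forward_project(ph, seq(0, 180, length.out = 121),
                        method = "discrete")
  vol <- reconstruct(ps)
  expect_identical(vol$source_role, "clean")
  expect_equal(dim(vol$voxels), rep(48L, 3))
  v <- phantom_voxels(ph)
  expect_gt(cor(as.vector(vol$voxels), as.vector(v)), 0.95)
  # the three phases land near their true gray values
  expect_lt(abs(median(vol$voxels[v == 0.3]) - 0.3), 0.03)
  expect_lt(abs(median(vol$voxels[v == 0]) - 0), 0.03)
})

test_that("the Parzen window tapers the ramp filter", {
  h_ramp <- fbp_filter(128, "ramp")
  h_par <- fbp_filter(128, "parzen")
  expect_true(all(h_par <= h_ramp + 1e-12))
  expect_lt(h_par[65] / h_ramp[65], 1e-6)   # fully suppressed at Nyquist
  expect_equal(h_par[2] / h_ramp[2], 1, tolerance = 0.01)  # untouched at DC+
})

test_that("degenerate reconstruction inputs are rejected", {
  ps <- fix_projections()
  expect_error(reconstruct_slice(matrix(ps$images[1, , 1], ncol = 1), 0),
               "two angles")
  bad <- ps
  bad$images[1, 1, 1] <- NaN
  expect_error(reconstruct(bad), "NA")
})
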