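test_that("phantom voxels take exactly the three phase values", {
  ph <- fix_phantom()
  v <- phantom_voxels(ph)
  expect_setequal(unique(as.vector(v)), c(0, 0.3, 1))
})

test_that("phantom generation is deterministic and respects its geometry", {
  a <- generate_phantom(48, 5, d_min = 4, d_max = 10, seed = 42)
  b <- generate_phantom(48, 5, d_min = 4, d_max = 10, seed = 42)
  expect_identical(a$spheres, b$spheres)
  expect_true(all(a$spheres$d >= 4 & a$spheres$d <= 10))
  # centres (with a radius margin) stay inside the cube
  r <- a$spheres$d / 2
  for (ax in c("x", "y", "z")) {
    expect_true(all(a$spheres[[ax]] - r >= a$cube_lo - 0.5))
    expect_true(all(a$spheres[[ax]] + r <= a$cube_hi + 0.5))
  }
  c <- generate_phantom(48, 5, d_min = 4, d_max = 10, seed = 43)
  expect_false(identical(a$spheres, c$spheres))
})

test_that("zero particles leave a pure two-phase cube", {
  ph <- generate_phantom(32, 0, seed = 1, d_min = 4, d_max = 8)
  v <- phantom_voxels(ph)
  expect_setequal(unique(as.vector(v)), c(0, 0.3))
})

test_that("a rasterised sphere holds its analytic voxel volume", {
  # diameter 8 -> (pi/6) 8^3 ~ 268 voxels, within 10%
  ph <- generate_phantom(64, 1, d_min = 8, d_max = 8, seed = 9)
  n1 <- sum(phantom_voxels(ph) == 1)
  expect_lt(abs(n1 - pi / 6 * 8^3), 0.1 * pi / 6 * 8^3)
})

test_that("invalid phantom parameters are rejected", {
  expect_error(generate_phantom(64, -1), "n_spheres")
  expect_error(generate_phantom(64, 1, d_min = 0, d_max = 8), "d_min")
  expect_error(generate_phantom(64, 1, d_min = 4, d_max = 50), "cube edge")
  expect_error(generate_phantom(10, 1, d_min = 4, d_max = 20), "at least")
})
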