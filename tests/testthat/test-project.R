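test_that("forward projection yields one image per angle at axis-sum scale", {
  ph <- fix_phantom()
  ps <- fix_projections()
  expect_equal(n_projections(ps), 61)
  expect_equal(ps$angles[1], 0)
  expect_equal(ps$angles[61], 180)
  # at 0 degrees the beam runs along y: projection = straight axis sum
  v <- phantom_voxels(ph)
  expect_equal(ps$images[, , 1], t(apply(v, c(1, 3), sum)), tolerance = 1e-12)
})

test_that("projection is linear and conserves per-slice mass", {
  ph <- fix_phantom()
  v <- phantom_voxels(ph)
  angles <- c(0, 30, 77.5, 120, 180)
  p1 <- forward_project(ph, angles, method = "discrete")
  ph2 <- ph; ph2$voxels <- 2.5 * v
  p2 <- forward_project(ph2, angles, method = "discrete")
  expect_equal(p2$images, 2.5 * p1$images, tolerance = 1e-12)
  ph0 <- ph; ph0$voxels <- v * 0
  expect_true(all(forward_project(ph0, angles,
                                  method = "discrete")$images == 0))
  # ray-sum total of each slice's projection is angle-independent
  mass <- apply(p1$images, c(1, 3), sum)   # slice x angle
  expect_lt(max(abs(mass - mass[, 1])), 1e-8 * max(mass))
})

test_that("closed-form and voxel projectors agree on the phantom model", {
  ph <- fix_phantom()
  angles <- seq(0, 180, length.out = 19)
  pd <- forward_project(ph, angles, method = "discrete")
  pa <- forward_project(ph, angles, method = "analytic")
  expect_gt(cor(as.vector(pd$images), as.vector(pa$images)), 0.995)
  expect_lt(sqrt(mean((pd$images - pa$images)^2)), 0.1 * sd(pd$images))
})

test_that("projection inputs are validated", {
  ph <- fix_phantom()
  expect_error(forward_project(ph, numeric(0)), "empty")
  expect_error(forward_project(ph, c(0, 190)), "within")
})

test_that("noise level scales with the global stack range", {
  ps <- fix_projections()
  lvl <- 0.3
  pn <- add_noise(ps, lvl, seed = 8)
  expect_identical(pn$role, "noisy")
  resid <- pn$images - ps$images
  expect_lt(abs(sd(resid) / (lvl * diff(range(ps$images))) - 1), 0.01)
  expect_lt(abs(mean(resid)), 0.01 * sd(resid))
  # deterministic per seed, fresh draw per seed
  expect_identical(pn$images, add_noise(ps, lvl, seed = 8)$images)
  expect_false(identical(pn$images, add_noise(ps, lvl, seed = 9)$images))
  # zero level returns the input unchanged
  expect_identical(add_noise(ps, 0)$images, ps$images)
  expect_error(add_noise(ps, -0.1), ">= 0")
  expect_error(add_noise(pn, 0.1), "clean")
})

test_that("averaging independent noise realisations converges like 1/sqrt(N)", {
  ps <- fix_projections()
  one <- function(s) add_noise(ps, 0.2, seed = s)$images - ps$images
  r1 <- sd(one(1))
  acc <- 0
  for (s in 1:16) acc <- acc + one(s)
  r16 <- sd(acc / 16)
  expect_lt(abs(r16 / (r1 / 4) - 1), 0.2)
})
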