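test_that("median filter rejects impulses and matches a loop oracle", {
  expect_equal(median_denoise(matrix(2, 9, 9)), matrix(2, 9, 9))
  img <- matrix(0.5, 11, 11)
  img[6, 6] <- 50
  expect_true(all(median_denoise(img, 3) == 0.5))
  set.seed(10)
  r <- matrix(runif(49), 7)
  out <- median_denoise(r, 3)
  refl <- function(i, n) { while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i; if (i > n) i <- 2 * n + 1 - i }; i }
  oracle <- matrix(0, 7, 7)
  for (a in 1:7) for (b in 1:7) {
    w <- numeric(0)
    for (da in -1:1) for (db in -1:1) {
      w <- c(w, r[refl(a + da, 7), refl(b + db, 7)])
    }
    oracle[a, b] <- median(w)
  }
  expect_equal(out, oracle)
  expect_error(median_denoise(r, 4), "odd")
})

test_that("TV denoising shrinks total variation and vanishes with weight", {
  set.seed(11)
  f <- matrix(0.3, 48, 48); f[15:35, 15:35] <- 1
  n <- f + matrix(rnorm(48 * 48, 0, 0.1), 48)
  u <- tv_denoise(n, 0.1, 100)
  expect_lt(total_variation(u), total_variation(n))
  expect_lt(sqrt(mean((u - f)^2)), sqrt(mean((n - f)^2)))
  # weight -> 0 converges to the input
  d <- vapply(c(1e-1, 1e-2, 2.5e-4), function(w) {
    max(abs(tv_denoise(n, w, 100) - n))
  }, 0)
  expect_true(all(diff(d) < 0))
  expect_lt(d[3], 1e-3)
  expect_error(tv_denoise(n, 0), "> 0")
})

test_that("stack denoising applies per image and validates roles", {
  ps <- fix_projections()
  pn <- add_noise(ps, 0.15, seed = 4)
  pm <- denoise_stack(pn, baseline_config("median", median_size = 3))
  expect_equal(pm$images[, , 2], median_denoise(pn$images[, , 2], 3))
  expect_identical(pm$denoise_method, "median")
  pt <- denoise_stack(pn, baseline_config("tv", tv_weight = 0.1,
                                          tv_iters = 30))
  expect_lt(mean((pt$images - ps$images)^2), mean((pn$images - ps$images)^2))
  expect_error(denoise_stack(ps, baseline_config("median")), "noisy")
  expect_error(baseline_config("median", median_size = 4), "odd")
  expect_error(baseline_config("tv", tv_weight = -1), "> 0")
})
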