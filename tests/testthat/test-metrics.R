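test_that("PSNR matches closed forms, caps, and is symmetric", {
  a <- matrix(runif(64), 8)
  expect_equal(psnr(a, a), 100)
  expect_equal(psnr(matrix(0.1, 4, 4), matrix(0, 4, 4)), 20)   # MSE 0.01
  expect_equal(psnr(a + 0.1, a, data_range = 1), 20)           # offset 0.1
  b <- matrix(runif(64), 8)
  expect_equal(psnr(a, b), psnr(b, a))
  expect_error(psnr(a, matrix(0, 4, 4)), "shape")
})

test_that("SSIM map agrees with a brute-force windowed computation", {
  set.seed(6)
  x <- matrix(runif(8 * 8), 8)
  y <- x + matrix(rnorm(64, 0, 0.1), 8)
  win <- 5; sig <- 1.5
  m <- ssim_map(x, y, window = win, sigma = sig)
  # independent loop oracle with the same symmetric reflection
  refl <- function(i, n) { while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i; if (i > n) i <- 2 * n + 1 - i }; i }
  k1 <- exp(-((1:win) - 3)^2 / (2 * sig^2)); k2 <- outer(k1, k1)
  k2 <- k2 / sum(k2)
  c1 <- 1e-4; c2 <- 9e-4
  oracle <- matrix(0, 8, 8)
  for (r in 1:8) for (cc in 1:8) {
    xs <- matrix(0, win, win); ys <- matrix(0, win, win)
    for (i in 1:win) for (j in 1:win) {
      xs[i, j] <- x[refl(r + i - 3, 8), refl(cc + j - 3, 8)]
      ys[i, j] <- y[refl(r + i - 3, 8), refl(cc + j - 3, 8)]
    }
    mu1 <- sum(k2 * xs); mu2 <- sum(k2 * ys)
    v1 <- sum(k2 * xs^2) - mu1^2; v2 <- sum(k2 * ys^2) - mu2^2
    cv <- sum(k2 * xs * ys) - mu1 * mu2
    oracle[r, cc] <- ((2 * mu1 * mu2 + c1) * (2 * cv + c2)) /
      ((mu1^2 + mu2^2 + c1) * (v1 + v2 + c2))
  }
  expect_equal(m, oracle, tolerance = 1e-10)
  expect_equal(ssim(x, y, window = win), mean(m))
})

test_that("SSIM behaves as a structural similarity should", {
  set.seed(7)
  x <- matrix(runif(32 * 32), 32)
  expect_true(all(abs(ssim_map(x, x) - 1) < 1e-9))
  # anti-correlated image scores poorly
  expect_lt(ssim(x, 1 - x), 0.2)
  # symmetric in its arguments
  y <- x + matrix(rnorm(1024, 0, 0.2), 32)
  expect_equal(ssim(x, y), ssim(y, x))
  # exactly invariant to a common positive rescaling with matched range
  expect_equal(ssim(2.5 * x, 2.5 * y, data_range = 2.5), ssim(x, y))
  expect_error(ssim_map(x, y, window = 4), "odd")
  expect_error(ssim_map(x, y, window = 41), "larger")
})

test_that("volume reports summarise per-slice quality", {
  set.seed(8)
  v <- array(runif(24^3), dim = rep(24, 3))
  rep0 <- volume_report(v, v)
  expect_equal(rep0$ssim_mean, 1)
  expect_equal(rep0$ssim_sd, 0)
  expect_equal(rep0$psnr_mean, 100)
  expect_equal(nrow(rep0$per_slice), 24)
  g <- glance(rep0)
  expect_equal(g$n_slices, 24)
  expect_error(volume_report(v, array(0, rep(12, 3))), "mismatch")
})

test_that("mode detection recovers planted mixture structure", {
  set.seed(9)
  # three well-separated phases with tomographic-like weights
  v3 <- c(rnorm(6e4, 0, 0.02), rnorm(3e4, 0.3, 0.02), rnorm(2e3, 1, 0.03))
  h3 <- histogram_modes(v3)
  expect_equal(h3$n_modes, 3)
  expect_equal(sort(h3$modes$value), c(0, 0.3, 1), tolerance = 0.05)
  # one broad peak once the noise floods the separation
  h1 <- histogram_modes(c(rnorm(9e4, 0.15, 0.5)))
  expect_equal(h1$n_modes, 1)
  expect_equal(histogram_modes(array(0.3, c(8, 8, 8)))$n_modes, 1)
  expect_error(histogram_modes(numeric(0)), "empty")
  expect_error(histogram_modes(v3, n_bins = 4), "n_bins")
})

test_that("a clean reconstruction's modes include the three phase values", {
  ph <- fix_phantom()
  ps <- forward_project(ph, seq(0, 180, length.out = 121),
                        method = "discrete")
  h <- histogram_modes(reconstruct(ps))
  # the background, cube and particle phases each produce a detected mode
  # (small-volume reconstructions may add a partial-volume band between the
  # cube and particle values, so the count is >= 3 rather than exactly 3)
  expect_gte(h$n_modes, 3)
  expect_true(any(abs(h$modes$value) < 0.06))
  expect_true(any(abs(h$modes$value - 0.3) < 0.06))
  expect_true(any(h$modes$value > 0.9))
  # the three phase peaks are the three most prominent ones
  top3 <- h$modes$value[order(-h$modes$prominence)][1:3]
  expect_lt(max(abs(sort(top3) - c(0, 0.3, 1))), 0.06)
})
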