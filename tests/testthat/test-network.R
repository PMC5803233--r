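test_that("network preserves shape and encodes at one-eighth scale", {
  m <- build_network(network_spec(patch_edge = 64), seed = 1)
  x <- matrix(runif(64 * 64), 64 * 64, 1)
  fwd <- tomodenoise:::cnn_forward(m, x, cache = TRUE)
  expect_equal(dim(fwd$out), c(64 * 64, 1))
  # input of the fully connected bottleneck sits at W/8 x H/8
  expect_equal(fwd$dims[[9]], c(8, 8))
  expect_equal(nrow(fwd$inputs[[9]]), 8 * 8 * 64)
  expect_error(network_spec(patch_edge = 20), "multiple of 8")
})

test_that("architecture counts follow the encoder-decoder layout", {
  spec <- network_spec()
  m <- build_network(spec, seed = 2)
  types <- vapply(m$layers, `[[`, "", "type")
  expect_equal(types, c(rep("conv", 8), "fc", rep("deconv", 9)))
  strides <- vapply(m$layers, `[[`, 0, "stride")
  expect_equal(sum(strides[1:8] == 2), 3)
  expect_equal(sum(strides[10:18] == 2), 3)
  expect_equal(m$layers[[18]]$cout, 1)
  kc <- vapply(m$layers[1:8], `[[`, 0, "cout")
  expect_true(all(kc >= 16 & kc <= 64) && kc[1] == 16 && kc[8] == 64)
})

test_that("initialisation is deterministic for a fixed seed", {
  x <- matrix(runif(32 * 32 * 2), 32 * 32, 2)
  a <- tomodenoise:::cnn_forward(build_network(network_spec(32), seed = 7), x)
  b <- tomodenoise:::cnn_forward(build_network(network_spec(32), seed = 7), x)
  expect_identical(a, b)
  d <- tomodenoise:::cnn_forward(build_network(network_spec(32), seed = 8), x)
  expect_false(identical(a, d))
})

test_that("inverse-PSNR loss matches its closed form and orders with MSE", {
  p <- matrix(0.1, 4, 4); t0 <- matrix(0, 4, 4)
  expect_equal(psnr_loss(p, t0, i_max = 1), 0.05)            # 20 dB
  p2 <- matrix(sqrt(0.1), 4, 4)
  expect_equal(psnr_loss(p2, t0, i_max = 1), 0.1)            # 10 dB
  expect_equal(psnr_loss(t0, t0, i_max = 1), 1 / 120)        # floored MSE
  mse <- 10^seq(-6, -0.5, length.out = 12)
  loss <- vapply(mse, function(m) {
    psnr_loss(matrix(sqrt(m), 2, 2), matrix(0, 2, 2))
  }, 0)
  expect_true(all(diff(loss) > 0))  # minimising 1/PSNR == minimising MSE
  expect_error(psnr_loss(p, matrix(0, 2, 2)), "shape")
})

test_that("backpropagation matches finite differences", {
  set.seed(4)
  m <- build_network(network_spec(16), seed = 3)
  X <- matrix(runif(16 * 16 * 2), 256, 2)
  Y <- matrix(runif(16 * 16 * 2), 256, 2)
  fwd <- tomodenoise:::cnn_forward(m, X, cache = TRUE)
  gr <- tomodenoise:::cnn_backward(m, fwd,
                                   tomodenoise:::psnr_loss_grad(fwd$out, Y))
  loss_at <- function(mm) psnr_loss(tomodenoise:::cnn_forward(mm, X), Y)
  eps <- 1e-6
  for (li in c(1, 2, 9, 12, 18)) {
    w <- m$layers[[li]]$W
    idx <- arrayInd(which.max(abs(gr[[li]]$W)), dim(w))
    mp <- m; mp$layers[[li]]$W[idx] <- w[idx] + eps
    mm2 <- m; mm2$layers[[li]]$W[idx] <- w[idx] - eps
    fd <- (loss_at(mp) - loss_at(mm2)) / (2 * eps)
    expect_lt(abs(fd - gr[[li]]$W[idx]) / max(abs(fd), 1e-10), 1e-4)
  }
})

test_that("training the identity mapping drives the validation MSE down", {
  ps <- fix_projections()
  img <- ps$images[, , 5]
  pairs <- list(list(low = img, high = img))
  m <- build_network(network_spec(16), seed = 2)
  m <- train_cnn(m, pairs, epochs = 10, batch_size = 8, patch_stride = 8,
                 seed = 3)
  expect_true(m$trained)
  expect_equal(nrow(m$log), 10)
  expect_lt(m$log$val_mse[10], 0.01)
  expect_lt(m$log$val_mse[10], m$log$val_mse[1] / 5)
})

test_that("a trained model denoises and preserves stack geometry", {
  fx <- fix_trained_tiny()
  pe <- enhance(fx$model, fx$noisy)
  expect_identical(pe$role, "enhanced")
  expect_equal(dim(pe$images), dim(fx$noisy$images))
  expect_identical(pe$angles, fx$noisy$angles)
  dr <- diff(range(fx$clean$images))
  s_noisy <- mean(vapply(seq_len(5), function(k) {
    ssim(fx$noisy$images[, , k], fx$clean$images[, , k], data_range = dr)
  }, 0))
  s_enh <- mean(vapply(seq_len(5), function(k) {
    ssim(pe$images[, , k], fx$clean$images[, , k], data_range = dr)
  }, 0))
  expect_gt(s_enh, s_noisy)
  expect_error(enhance(build_network(network_spec(16)), fx$noisy),
               "untrained")
})

test_that("skip merges preserve high-frequency detail (ablation)", {
  ps <- fix_projections()
  pn <- add_noise(ps, 0.2, seed = 3)
  pairs <- training_pairs(pn, ps, c(0, 45))
  hf_energy <- function(img) {
    f <- Mod(fft(img))^2
    n <- nrow(img)
    idx <- c((n %/% 4):(3 * n %/% 4))
    sum(f[idx, ]) + sum(f[-idx, idx])
  }
  sub <- pn
  sub$images <- pn$images[, , c(10, 30), drop = FALSE]
  sub$angles <- pn$angles[c(10, 30)]
  fit <- function(merges) {
    m <- build_network(network_spec(16, merges = merges), seed = 5)
    m <- train_cnn(m, pairs, epochs = 6, batch_size = 16, patch_stride = 8,
                   seed = 7)
    pe <- enhance(m, sub)
    mean(vapply(1:2, function(k) hf_energy(pe$images[, , k]), 0))
  }
  expect_gt(fit(TRUE), fit(FALSE))
})

test_that("weight snapshots restore the model state at a given epoch", {
  ps <- fix_projections()
  img <- ps$images[, , 3]
  pairs <- list(list(low = img + 1, high = img))
  m <- build_network(network_spec(16), seed = 2)
  m <- train_cnn(m, pairs, epochs = 4, batch_size = 8, patch_stride = 16,
                 seed = 3, snapshot_epochs = 2)
  m2 <- model_at_epoch(m, 2)
  expect_equal(nrow(m2$log), 2)
  expect_false(identical(m2$layers, m$layers))
  expect_error(model_at_epoch(m, 3), "no snapshot")
})
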