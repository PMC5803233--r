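test_that("two-step normalization maps onto [0,1] and inverts exactly", {
  set.seed(1)
  img <- matrix(rnorm(32 * 32, 50, 12), 32)
  nz <- normalize_two_step(img)
  expect_equal(min(nz$image), 0)
  expect_equal(max(nz$image), 1)
  back <- denormalize_two_step(nz$image, nz$params)
  expect_lt(max(abs(back - img)) / diff(range(img)), 1e-6)
  # oracle: both formulas applied directly
  i1 <- (img - mean(img)) / sd(img)
  expect_equal(nz$image, (i1 - min(i1)) / (max(i1) - min(i1)))
})

test_that("normalization is invariant to positive affine rescaling", {
  set.seed(2)
  img <- matrix(runif(24 * 24), 24)
  a <- normalize_two_step(img)$image
  b <- normalize_two_step(3.7 * img + 11)$image
  expect_equal(a, b, tolerance = 1e-12)
  expect_error(normalize_two_step(matrix(5, 8, 8)), "constant")
})

test_that("patch extraction matches brute-force anchor enumeration", {
  # 64x64 with patch 64: a single patch equal to the image
  img <- matrix(seq_len(64 * 64), 64)
  px <- extract_patches(img, 64, 16)
  expect_equal(dim(px$patches)[3], 1)
  expect_equal(px$patches[, , 1], img)
  # 512x512, patch 64, stride 16 -> 29 x 29 anchors
  big <- matrix(0, 512, 512)
  grid <- extract_patches(big, 64, 16)$grid
  anchors <- seq(1, 512 - 64 + 1, by = 16)   # oracle enumeration
  expect_equal(nrow(grid$anchors), length(anchors)^2)
  expect_equal(sort(unique(grid$anchors$row)), anchors)
  # clamped final anchor covers the far edge on non-divisible sizes
  g2 <- extract_patches(matrix(0, 70, 70), 32, 16)$grid
  expect_true(39 %in% g2$anchors$row)
  expect_error(extract_patches(img, 60, 16), "multiple of 8")
})

test_that("patch count is nonincreasing in stride", {
  img <- matrix(0, 96, 96)
  n <- vapply(c(4, 8, 16, 32), function(s) {
    nrow(extract_patches(img, 32, s)$grid$anchors)
  }, 0)
  expect_true(all(diff(n) <= 0))
})

test_that("patch reassembly averages overlaps and inverts extraction", {
  set.seed(3)
  img <- matrix(rnorm(70 * 58), 70, 58)
  px <- extract_patches(img, 32, 8)
  back <- reassemble_patches(px$patches, px$grid)
  expect_lt(max(abs(back - img)), 1e-6)
  # two half-overlapping constant patches average to 0.5 in the overlap
  base <- matrix(0, 32, 48)
  px2 <- extract_patches(base, 32, 16)
  expect_equal(nrow(px2$grid$anchors), 2)
  px2$patches[, , 1] <- 0
  px2$patches[, , 2] <- 1
  out <- reassemble_patches(px2$patches, px2$grid)
  expect_true(all(out[, 1:16] == 0))
  expect_true(all(out[, 17:32] == 0.5))
  expect_true(all(out[, 33:48] == 1))
  # oracle: accumulate sums and counts per pixel by loop
  acc <- matrix(0, 70, 58); cnt <- matrix(0, 70, 58)
  for (i in seq_len(dim(px$patches)[3])) {
    r <- px$grid$anchors$row[i]; cc <- px$grid$anchors$col[i]
    ri <- r:(r + 31); ci <- cc:(cc + 31)
    acc[ri, ci] <- acc[ri, ci] + px$patches[, , i]
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  expect_equal(back, acc / cnt, tolerance = 1e-12)
  expect_error(reassemble_patches(px$patches[, , 1:3], px$grid), "match")
})
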