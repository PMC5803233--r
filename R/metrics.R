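#' Peak signal-to-noise ratio
#'
#' Conventional evaluation PSNR, `10 log10(data_range^2 / MSE)` in dB, capped
#' at 100 dB for identical images.
#'
#' @param test,reference numeric arrays of identical shape.
#' @param data_range peak-to-peak intensity range of the data.
#' @return PSNR in dB.
#' @examples
#' psnr(matrix(0.1, 4, 4), matrix(0, 4, 4))  # MSE 0.01 -> 20 dB
#' @export
psnr <- function(test, reference, data_range = 1) {
  if (!identical(dim(test), dim(reference))) stop("shape mismatch")
  mse <- mean((test - reference)^2)
  if (mse == 0) return(100)
  min(10 * log10(data_range^2 / mse), 100)
}

gaussian_kernel <- function(window = 11, sigma = 1.5) {
  x <- seq_len(window) - (window + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Per-pixel structural similarity map
#'
#' Standard SSIM with a Gaussian weighting window (11x11, sigma 1.5 by
#' default) and stabilisers `C1 = (0.01 data_range)^2`,
#' `C2 = (0.03 data_range)^2`. Local statistics use symmetric boundary
#' reflection, so the map has the same shape as the inputs; its mean is the
#' global SSIM score.
#'
#' @param test,reference numeric matrices of identical shape.
#' @param window odd window size in pixels.
#' @param sigma Gaussian window width.
#' @param data_range intensity range of the data.
#' @return matrix of per-pixel SSIM values (at most 1).
#' @export
ssim_map <- function(test, reference, window = 11, sigma = 1.5,
                     data_range = 1) {
  stop_if_not_matrix(test, "test"); stop_if_not_matrix(reference, "reference")
  if (!identical(dim(test), dim(reference))) stop("shape mismatch")
  if (window %% 2 == 0) stop("window must be odd")
  if (window > min(dim(test))) stop("window larger than image")
  k <- gaussian_kernel(window, sigma)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  mu1 <- cpp_sep_filter(test, k)
  mu2 <- cpp_sep_filter(reference, k)
  s11 <- cpp_sep_filter(test * test, k) - mu1^2
  s22 <- cpp_sep_filter(reference * reference, k) - mu2^2
  s12 <- cpp_sep_filter(test * reference, k) - mu1 * mu2
  ((2 * mu1 * mu2 + c1) * (2 * s12 + c2)) /
    ((mu1^2 + mu2^2 + c1) * (s11 + s22 + c2))
}

#' Global structural similarity score
#'
#' Mean of the [ssim_map()].
#'
#' @inheritParams ssim_map
#' @export
ssim <- function(test, reference, window = 11, sigma = 1.5, data_range = 1) {
  mean(ssim_map(test, reference, window, sigma, data_range))
}

#' Slice-wise quality report for a reconstructed volume
#'
#' Computes PSNR and SSIM of every slice of `test` against the matching slice
#' of `reference`, plus their means and standard deviations across slices.
#'
#' @param test,reference `tomo_volume`s (or 3-D arrays) of equal shape.
#' @param data_range intensity range used by both metrics.
#' @param window SSIM window size.
#' @return a `quality_report`: list with `per_slice` tibble
#'   (`slice`, `psnr`, `ssim`) and scalar `psnr_mean`, `psnr_sd`,
#'   `ssim_mean`, `ssim_sd`.
#' @export
volume_report <- function(test, reference, data_range = 1, window = 11) {
  tv <- if (inherits(test, "tomo_volume")) test$voxels else test
  rv <- if (inherits(reference, "tomo_volume")) reference$voxels else
    reference
  if (!identical(dim(tv), dim(rv))) stop("volume shape mismatch")
  n <- dim(tv)[3]
  ps <- numeric(n); ss <- numeric(n)
  for (z in seq_len(n)) {
    ps[z] <- psnr(tv[, , z], rv[, , z], data_range)
    ss[z] <- ssim(tv[, , z], rv[, , z], window = window,
                  data_range = data_range)
  }
  structure(list(per_slice = tibble::tibble(slice = seq_len(n), psnr = ps,
                                            ssim = ss),
                 psnr_mean = mean(ps), psnr_sd = sd(ps),
                 ssim_mean = mean(ss), ssim_sd = sd(ss)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report> ", nrow(x$per_slice), " slices: PSNR ",
      round(x$psnr_mean, 2), " +/- ", round(x$psnr_sd, 2), " dB, SSIM ",
      round(x$ssim_mean, 3), " +/- ", round(x$ssim_sd, 3), "\n", sep = "")
  invisible(x)
}

# moving average with shrinking window at the edges
smooth_counts <- function(x, width = 5) {
  h <- width %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - h):min(n, i + h)])
  }, 0)
}

# topographic prominence of each local maximum of y (boundary bins can be
# peaks too: a phase at the edge of the intensity range still counts)
peak_prominences <- function(y) {
  n <- length(y)
  peaks <- which(vapply(seq_len(n), function(i) {
    (i == 1L || y[i] > y[i - 1]) && (i == n || y[i] >= y[i + 1])
  }, TRUE))
  prom <- vapply(peaks, function(p) {
    side_key <- function(idx) {
      if (length(idx) == 0) return(NA_real_)
      m <- Inf
      for (i in idx) {
        if (y[i] > y[p]) return(m)
        m <- min(m, y[i])
      }
      NA_real_  # no higher terrain on this side
    }
    lk <- side_key(rev(seq_len(p - 1)))
    rk <- side_key(if (p < n) seq(p + 1, n) else integer(0))
    key <- if (is.na(lk) && is.na(rk)) min(y) else max(lk, rk, na.rm = TRUE)
    y[p] - key
  }, 0)
  tibble::tibble(bin = peaks, height = y[peaks], prominence = prom)
}

#' Histogram of a volume with mode detection
#'
#' Histograms all voxels and counts the "distinguished peaks": the counts are
#' smoothed with a 5-bin moving average, mapped to a log scale
#' (`log10(1 + count)` — peak *visibility* in a tomographic histogram is a
#' ratio phenomenon, since the particle phase holds a tiny fraction of the
#' voxels), and local maxima whose topographic prominence on that scale
#' exceeds `prominence` (0.5, i.e. the peak stands a factor ~3 above its key
#' saddle) are counted as modes, subject to two guards: the peak must hold at
#' least `min_height_frac` of the tallest smoothed bin (discarding
#' near-empty-bin ripple that the log scale would otherwise amplify), and
#' candidate peaks closer than `min_separation` bins are merged into the
#' taller one (filtered backprojection produces narrow edge-response bands
#' that hug the phase peaks; "distinguished" peaks are the ones separated on
#' the scale of the phase contrast). A clean three-phase reconstruction shows
#' 3 modes; heavy noise merges them into one broad peak.
#'
#' @param volume a `tomo_volume` or numeric array.
#' @param n_bins number of histogram bins (>= 8).
#' @param smooth_width moving-average width in bins.
#' @param prominence log10 prominence threshold for a peak to count.
#' @param min_height_frac minimum smoothed count of a mode, as a fraction of
#'   the tallest smoothed bin.
#' @param min_separation minimum distance between modes, in bins; defaults to
#'   an eighth of the intensity range.
#' @return a `tomo_histogram`: bin edges, raw counts, smoothed log counts,
#'   the detected `modes` tibble and `n_modes`.
#' @export
histogram_modes <- function(volume, n_bins = 256, smooth_width = 9,
                            prominence = 0.5, min_height_frac = 1e-4,
                            min_separation = n_bins %/% 8) {
  v <- if (inherits(volume, "tomo_volume")) volume$voxels else volume
  if (length(v) == 0) stop("empty volume")
  if (n_bins < 8) stop("n_bins must be >= 8")
  rng <- range(v)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  # pad by two empty bins so a phase sitting at the intensity extreme forms
  # an interior peak rather than an invisible boundary maximum
  pad <- 2 * diff(rng) / n_bins
  edges <- seq(rng[1] - pad, rng[2] + pad, length.out = n_bins + 1)
  counts <- tabulate(findInterval(v, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  sm <- smooth_counts(counts, smooth_width)
  s <- log10(1 + sm)
  pk <- peak_prominences(s)
  cand <- pk[pk$prominence >= prominence &
               sm[pk$bin] >= min_height_frac * max(sm), , drop = FALSE]
  # greedy suppression: taller peaks absorb candidates within min_separation
  cand <- cand[order(-cand$height), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    keep[i] <- !any(abs(cand$bin[keep] - cand$bin[i]) < min_separation)
  }
  modes <- cand[keep, , drop = FALSE]
  modes <- modes[order(modes$bin), , drop = FALSE]
  modes$value <- (edges[modes$bin] + edges[modes$bin + 1]) / 2
  structure(list(edges = edges, counts = counts, smoothed_log = s,
                 modes = modes, n_modes = nrow(modes)),
            class = "tomo_histogram")
}

#' @export
print.tomo_histogram <- function(x, ...) {
  cat("<tomo_histogram> ", length(x$counts), " bins, ", x$n_modes,
      " mode(s) at ", paste(signif(x$modes$value, 3), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
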