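#' Baseline denoiser configuration
#'
#' @param method `"median"` or `"tv"`.
#' @param median_size odd sliding-window size (pixels) for the median filter.
#' @param tv_weight total-variation regularisation strength, as a fraction of
#'   each image's dynamic range (applied per image by [denoise_stack()]).
#' @param tv_iters iteration budget of the dual-projection TV solver.
#' @export
baseline_config <- function(method = c("median", "tv"), median_size = 3,
                            tv_weight = 0.1, tv_iters = 100) {
  method <- match.arg(method)
  if (median_size %% 2 == 0 || median_size < 3) {
    stop("median_size must be odd and >= 3")
  }
  if (tv_weight <= 0) stop("tv_weight must be > 0")
  structure(list(method = method, median_size = as.integer(median_size),
                 tv_weight = tv_weight, tv_iters = as.integer(tv_iters)),
            class = "baseline_config")
}

#' Total-variation denoising (Rudin-Osher-Fatemi model)
#'
#' Minimises `||u - f||^2 / 2 + weight * TV(u)` with Chambolle's dual
#' projection algorithm at a fixed iteration budget. The result never has
#' larger total variation than the input, and as `weight -> 0` it converges
#' to the input.
#'
#' @param image numeric matrix.
#' @param weight regularisation strength (intensity units).
#' @param n_iter number of dual iterations.
#' @param tau dual step size (0.25 guarantees convergence).
#' @return denoised matrix.
#' @export
tv_denoise <- function(image, weight = 0.1, n_iter = 100, tau = 0.25) {
  stop_if_not_matrix(image, "image")
  if (weight <= 0) stop("weight must be > 0")
  d <- dim(image)
  p1 <- matrix(0, d[1], d[2])
  p2 <- matrix(0, d[1], d[2])
  grad_x <- function(u) rbind(u[-1, , drop = FALSE], u[d[1], , drop = FALSE]) - u
  grad_y <- function(u) cbind(u[, -1, drop = FALSE], u[, d[2], drop = FALSE]) - u
  divergence <- function(p1, p2) {
    dx <- p1 - rbind(0, p1[-d[1], , drop = FALSE])
    dx[d[1], ] <- -p1[d[1] - 1, ]
    dy <- p2 - cbind(0, p2[, -d[2], drop = FALSE])
    dy[, d[2]] <- -p2[, d[2] - 1]
    dx + dy
  }
  for (i in seq_len(n_iter)) {
    u <- image - weight * divergence(p1, p2)
    gx <- grad_x(u)
    gy <- grad_y(u)
    denom <- 1 + (tau / weight) * sqrt(gx^2 + gy^2)
    p1 <- (p1 - (tau / weight) * gx) / denom
    p2 <- (p2 - (tau / weight) * gy) / denom
  }
  image - weight * divergence(p1, p2)
}

#' Median-filter denoising
#'
#' Sliding-window median with symmetric edge reflection.
#'
#' @param image numeric matrix.
#' @param size odd window size.
#' @export
median_denoise <- function(image, size = 3) {
  stop_if_not_matrix(image, "image")
  if (size %% 2 == 0) stop("median window must be odd")
  cpp_median_filter(image, as.integer(size))
}

#' Denoise every projection of a stack with a classical baseline
#'
#' Applies the configured baseline (median filter or TV regularisation) image
#' by image. These are the classical comparators for the learned enhancement.
#'
#' @param projections a `projection_set` with role `"noisy"` or
#'   `"measured_short"`.
#' @param config a [baseline_config()].
#' @return a `projection_set` of the same geometry/role, with the applied
#'   method recorded in `$denoise_method`.
#' @export
denoise_stack <- function(projections, config = baseline_config()) {
  stopifnot(inherits(projections, "projection_set"),
            inherits(config, "baseline_config"))
  if (!projections$role %in% c("noisy", "measured_short")) {
    stop("denoise_stack expects noisy or measured_short projections")
  }
  out <- projections
  for (k in seq_len(dim(out$images)[3])) {
    img <- projections$images[, , k]
    out$images[, , k] <- switch(config$method,
      median = median_denoise(img, config$median_size),
      # tv_weight is relative to the image's dynamic range, so one default
      # works for unit-scaled and line-integral-scaled stacks alike
      tv = tv_denoise(img, config$tv_weight * max(diff(range(img)), 1e-12),
                      config$tv_iters))
  }
  out$denoise_method <- config$method
  out
}

#' Total variation of an image
#'
#' Sum of the Euclidean norms of the forward-difference gradients; the
#' quantity the TV baseline penalises.
#'
#' @param image numeric matrix.
#' @export
total_variation <- function(image) {
  d <- dim(image)
  gx <- rbind(image[-1, , drop = FALSE], image[d[1], , drop = FALSE]) - image
  gy <- cbind(image[, -1, drop = FALSE], image[, d[2], drop = FALSE]) - image
  sum(sqrt(gx^2 + gy^2))
}
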