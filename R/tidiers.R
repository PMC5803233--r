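#' Tidy a trained network's training history
#'
#' @param x a `tomo_cnn`.
#' @param ... unused.
#' @return tibble with one row per epoch (`epoch`, `train_loss`,
#'   `train_mse`, `val_mse`).
#' @export
tidy.tomo_cnn <- function(x, ...) {
  if (is.null(x$log)) return(tibble::tibble(epoch = integer(), train_loss = double(),
                                            train_mse = double(), val_mse = double()))
  x$log
}

#' One-row summary of a trained network
#'
#' @param x a `tomo_cnn`.
#' @param ... unused.
#' @export
glance.tomo_cnn <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l) length(l$W) + length(l$b), 0))
  last <- if (is.null(x$log)) tibble::tibble(epoch = 0L, train_mse = NA_real_,
                                             val_mse = NA_real_)
          else x$log[nrow(x$log), ]
  tibble::tibble(patch_edge = x$patch_edge, n_parameters = np,
                 trained = x$trained, epochs = last$epoch,
                 train_mse = last$train_mse, val_mse = last$val_mse)
}

#' Per-slice metrics of a quality report
#' @param x a `quality_report`.
#' @param ... unused.
#' @export
tidy.quality_report <- function(x, ...) x$per_slice

#' One-row summary of a quality report
#' @param x a `quality_report`.
#' @param ... unused.
#' @export
glance.quality_report <- function(x, ...) {
  tibble::tibble(psnr_mean = x$psnr_mean, psnr_sd = x$psnr_sd,
                 ssim_mean = x$ssim_mean, ssim_sd = x$ssim_sd,
                 n_slices = nrow(x$per_slice))
}

#' @rdname tidy.quality_report
#' @export
tidy.noise_benchmark <- function(x, ...) x$per_slice

#' @rdname glance.quality_report
#' @export
glance.noise_benchmark <- function(x, ...) {
  tibble::tibble(psnr_mean = x$psnr_mean, psnr_sd = x$psnr_sd,
                 ssim_mean = x$ssim_mean, ssim_sd = x$ssim_sd,
                 sigma = x$sigma, n_slices = nrow(x$per_slice))
}

#' Tidy an experiment's summary table
#' @param x a `tomo_experiment`.
#' @param ... unused.
#' @export
tidy.tomo_experiment <- function(x, ...) x$summary
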