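#' Plot slice-wise quality metrics
#'
#' Per-slice PSNR and SSIM curves of a [volume_report()] or of the streaming
#' [noise_reconstruction_benchmark()].
#'
#' @param object a `quality_report` or `noise_benchmark`.
#' @param ... unused.
#' @export
autoplot.quality_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_slice, c("psnr", "ssim"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$slice, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(psnr = "PSNR (dB)", ssim = "SSIM"))) +
    ggplot2::labs(x = "slice", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.quality_report
#' @export
autoplot.noise_benchmark <- function(object, ...) {
  autoplot.quality_report(object, ...)
}

#' Plot the training history of a network
#'
#' @param object a trained `tomo_cnn`.
#' @param ... unused.
#' @export
autoplot.tomo_cnn <- function(object, ...) {
  if (is.null(object$log)) stop("model has no training log")
  df <- tidyr::pivot_longer(object$log, c("train_mse", "val_mse"),
                            names_to = "series")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "MSE", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a volume histogram with detected modes
#'
#' @param object a `tomo_histogram` from [histogram_modes()].
#' @param ... unused.
#' @export
autoplot.tomo_histogram <- function(object, ...) {
  mids <- (object$edges[-1] + object$edges[-length(object$edges)]) / 2
  df <- tibble::tibble(value = mids, count = object$counts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$count)) +
    ggplot2::geom_col(width = diff(object$edges)[1], fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$modes$value,
                        colour = "firebrick", linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "gray value", y = "voxel count") +
    ggplot2::theme_minimal()
}
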