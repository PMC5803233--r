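#' Encoder-decoder network architecture
#'
#' Describes the image-to-image regression network: an encoder of 8
#' convolutional layers (3x3 kernels, kernel counts growing 16 to 64, three
#' layers with 2x2 stride halving the spatial size down to W/8 x H/8)
#' followed by a shape-preserving fully connected bottleneck, and a decoder of
#' 9 transposed-convolution layers (3x3 kernels, kernel counts shrinking 64 to
#' 1, three stride-2 layers doubling the size back up). After each stride-2
#' decoder stage the feature maps are concatenated ("merged") with the encoder
#' activations of the same spatial scale, so full-resolution detail bypasses
#' the bottleneck and the output stays sharp. Every layer uses a rectified
#' linear activation.
#'
#' Layer schedule (input edge E): encoder kernel counts
#' `16, 16, 32, 32, 32, 64, 64, 64` with stride 2 at layers 2, 4 and 6; the
#' bottleneck maps the flattened `(E/8)^2 x 64` encoding to an equal-sized
#' vector; decoder kernel counts `64, 64, 64, 32, 32, 32, 16, 16, 1` with
#' stride 2 at layers 3, 5 and 7 and merges from encoder layers 5, 3 and 1.
#'
#' @param patch_edge input/output edge in pixels; multiple of 8.
#' @param merges logical; set `FALSE` to ablate the skip merges.
#' @return a `network_spec`.
#' @export
network_spec <- function(patch_edge = 64, merges = TRUE) {
  if (patch_edge %% 8 != 0) stop("patch_edge must be a multiple of 8")
  enc <- list(c(16, 1), c(16, 2), c(32, 1), c(32, 2),
              c(32, 1), c(64, 2), c(64, 1), c(64, 1))
  dec <- list(c(64, 1), c(64, 1), c(64, 2), c(32, 1),
              c(32, 2), c(32, 1), c(16, 2), c(16, 1), c(1, 1))
  structure(list(patch_edge = patch_edge, encoder = enc, decoder = dec,
                 merge_links = if (merges) c(`3` = 5L, `5` = 3L, `7` = 1L)
                               else setNames(integer(0), character(0)),
                 activation = "relu"),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec> input ", x$patch_edge, "x", x$patch_edge,
      ", 8 conv + FC + 9 deconv, merges: ",
      if (length(x$merge_links)) "on" else "off", "\n", sep = "")
  invisible(x)
}

#' Build an (untrained) enhancement network
#'
#' Allocates and initialises all weights for a [network_spec()]. Convolution
#' and transposed-convolution weights use He-scaled Gaussian initialisation
#' (`sd = sqrt(2 / fan_in)`), biases start at zero; initialisation is
#' deterministic for a fixed seed.
#'
#' @param spec a `network_spec` (default architecture if omitted).
#' @param seed integer RNG seed for the parameter draw.
#' @return a `tomo_cnn` model object (untrained).
#' @examples
#' m <- build_network(network_spec(patch_edge = 16), seed = 1)
#' @export
build_network <- function(spec = network_spec(), seed = 1) {
  stopifnot(inherits(spec, "network_spec"))
  e <- spec$patch_edge
  layers <- list()
  with_seed(seed, {
    cin <- 1L
    for (i in seq_along(spec$encoder)) {
      cout <- spec$encoder[[i]][1]; stride <- spec$encoder[[i]][2]
      layers[[length(layers) + 1L]] <- list(
        type = "conv", cin = cin, cout = cout, stride = stride,
        W = matrix(rnorm(cout * 9 * cin, 0, sqrt(2 / (9 * cin))),
                   cout, 9 * cin),
        b = numeric(cout))
      cin <- cout
    }
    f <- as.integer((e / 8)^2 * 64)
    layers[[length(layers) + 1L]] <- list(
      type = "fc", cin = f, cout = f, stride = 1L,
      W = matrix(rnorm(f * f, 0, sqrt(2 / f)), f, f), b = numeric(f))
    cin <- 64L
    for (i in seq_along(spec$decoder)) {
      cout <- spec$decoder[[i]][1]; stride <- spec$decoder[[i]][2]
      layers[[length(layers) + 1L]] <- list(
        type = "deconv", cin = cin, cout = cout, stride = stride,
        W = matrix(rnorm(9 * cout * cin, 0, sqrt(2 / (9 * cin))),
                   9 * cout, cin),
        b = numeric(cout))
      cin <- cout
      link <- spec$merge_links[as.character(i)]
      if (!is.na(link) && length(link)) {
        cin <- cin + spec$encoder[[link]][1]   # concat widens the next input
      }
    }
  })
  structure(list(spec = spec, layers = layers, patch_edge = e,
                 trained = FALSE, log = NULL, snapshots = NULL, seed = seed),
            class = "tomo_cnn")
}

#' @export
print.tomo_cnn <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l) length(l$W) + length(l$b), 0))
  cat("<tomo_cnn> patch ", x$patch_edge, "x", x$patch_edge, ", ",
      format(np, big.mark = ","), " parameters, ",
      if (x$trained) "trained" else "untrained", "\n", sep = "")
  if (!is.null(x$log)) {
    last <- x$log[nrow(x$log), ]
    cat("  epochs: ", last$epoch, ", train MSE ",
        signif(last$train_mse, 3), ", val MSE ", signif(last$val_mse, 3),
        "\n", sep = "")
  }
  invisible(x)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Forward pass over a batch. X: (patch_edge^2) x N matrix, one flattened
# single-channel patch per column. Returns the output batch, or (with cache)
# everything the backward pass needs.
cnn_forward <- function(model, X, cache = FALSE) {
  spec <- model$spec
  e <- model$patch_edge
  n_enc <- length(spec$encoder)
  inputs <- vector("list", length(model$layers))
  outputs <- vector("list", length(model$layers))
  dims <- vector("list", length(model$layers))
  enc_out <- vector("list", n_enc)  # post-activation encoder maps (for merges)
  h <- e; w <- e
  cur <- X
  for (i in seq_len(n_enc)) {
    l <- model$layers[[i]]
    if (cache) { inputs[[i]] <- cur; dims[[i]] <- c(h, w) }
    cur <- relu(cpp_conv_fwd(cur, l$W, l$b, h, w, l$cin, l$stride))
    h <- (h - 1) %/% l$stride + 1L; w <- (w - 1) %/% l$stride + 1L
    if (cache) outputs[[i]] <- cur
    enc_out[[i]] <- cur
  }
  ifc <- n_enc + 1L
  lfc <- model$layers[[ifc]]
  if (cache) { inputs[[ifc]] <- cur; dims[[ifc]] <- c(h, w) }
  cur <- relu(lfc$W %*% cur + lfc$b)
  if (cache) outputs[[ifc]] <- cur
  for (j in seq_along(spec$decoder)) {
    i <- ifc + j
    l <- model$layers[[i]]
    if (cache) { inputs[[i]] <- cur; dims[[i]] <- c(h, w) }
    cur <- relu(cpp_deconv_fwd(cur, l$W, l$b, h, w, l$cin, l$stride))
    h <- h * l$stride; w <- w * l$stride
    if (cache) outputs[[i]] <- cur
    link <- spec$merge_links[as.character(j)]
    if (!is.na(link) && length(link)) {
      cur <- rbind(cur, enc_out[[link]])
    }
  }
  if (!cache) return(cur)
  list(out = cur, inputs = inputs, outputs = outputs, dims = dims)
}

#' Inverse-PSNR training objective
#'
#' The network is trained by minimising `1 / PSNR` with
#' `PSNR = 10 log10(i_max / MSE)` (`i_max` unsquared; on normalized unit-range
#' data with `i_max = 1` this coincides with the conventional definition).
#' The MSE is floored at `mse_floor` so a perfect prediction yields a large
#' finite PSNR instead of a division blow-up.
#'
#' @param prediction,target numeric arrays of identical shape.
#' @param i_max peak intensity (1 after normalization).
#' @param mse_floor lower bound applied to the MSE.
#' @return scalar loss value `1 / PSNR`.
#' @examples
#' psnr_loss(matrix(0.1, 2, 2), matrix(0, 2, 2), i_max = 1)  # PSNR 20 dB
#' @export
psnr_loss <- function(prediction, target, i_max = 1, mse_floor = 1e-12) {
  if (!identical(dim(prediction), dim(target))) stop("shape mismatch")
  if (i_max <= 0) stop("i_max must be positive")
  mse <- max(mean((prediction - target)^2), mse_floor)
  1 / (10 * log10(i_max / mse))
}
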